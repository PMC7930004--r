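#' Cohen's d from group summaries
#'
#' Standardised mean difference using the pooled standard deviation,
#' \eqn{d = (m_1 - m_2)/s_p} with
#' \eqn{s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return Cohen's d (positive when group 1 scores higher).
#' @export
cohens_d_summary <- function(m1, s1, n1, m2, s2, n2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  (m1 - m2) / sp
}

#' Engagement rate from a task-count summary
#'
#' @param mean_total Mean number of task responses over the session.
#' @param minutes Session duration in minutes.
#' @return Responses per minute.
#' @export
engagement_rate <- function(mean_total, minutes) mean_total / minutes

#' Manipulation check on subjective workload ratings
#'
#' One-way ANOVA (two groups) per questionnaire item and for the global
#' score (mean of the items), with Cohen's d from the pooled SD. Subjects
#' with a missing value on an item are excluded from that item's test
#' (listwise per item).
#'
#' @param ratings Numeric matrix or data frame, one row per subject, one
#'   column per item (0-10 scale).
#' @param group Factor or character: two groups, e.g. control/task.
#' @return Data frame with one row per item plus `global`: `item`, `f`,
#'   `df1`, `df2`, `p`, `d`, group means and SDs. Items with zero variance
#'   in both groups get `NA` statistics.
#' @export
manipulation_check <- function(ratings, group) {
  ratings <- as.matrix(ratings)
  if (any(ratings < 0 | ratings > 10, na.rm = TRUE))
    stop("ratings must be on a 0-10 scale", call. = FALSE)
  group <- droplevels(factor(group))
  if (nlevels(group) != 2 || min(table(group)) < 2)
    stop("need two groups with at least 2 subjects each", call. = FALSE)
  g1 <- levels(group)[1]; g2 <- levels(group)[2]
  items <- cbind(ratings, global = rowMeans(ratings))
  one <- function(v, nm) {
    ok <- is.finite(v)
    v <- v[ok]; g <- droplevels(group[ok])
    n1 <- sum(g == g1); n2 <- sum(g == g2)
    m1 <- mean(v[g == g1]); m2 <- mean(v[g == g2])
    s1 <- stats::sd(v[g == g1]); s2 <- stats::sd(v[g == g2])
    if ((s1 == 0 && s2 == 0) || n1 < 2 || n2 < 2)
      return(data.frame(item = nm, f = NA_real_, df1 = 1,
                        df2 = n1 + n2 - 2, p = NA_real_,
                        d = if (s1 == 0 && s2 == 0 && m1 == m2) 0 else NA_real_,
                        mean_1 = m1, sd_1 = s1, mean_2 = m2, sd_2 = s2))
    a <- stats::anova(stats::lm(v ~ g))
    data.frame(item = nm, f = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
               p = a$`Pr(>F)`[1],
               d = cohens_d_summary(m2, s2, n2, m1, s1, n1),
               mean_1 = m1, sd_1 = s1, mean_2 = m2, sd_2 = s2)
  }
  out <- do.call(rbind, lapply(colnames(items), function(nm)
    one(items[, nm], nm)))
  attr(out, "groups") <- c(g1, g2)
  out
}

#' Simulate subjective workload ratings and task-engagement counts
#'
#' Synthetic stand-in for questionnaire and task-performance data: item
#' ratings are gaussian around group-level item means (clipped to the 0-10
#' scale), and per-subject task-response totals are gaussian for the task
#' group only.
#'
#' @param n_task,n_control Group sizes.
#' @param item_means_task,item_means_control Length-6 item means.
#' @param item_sd_task,item_sd_control Common item SDs per group.
#' @param count_mean,count_sd Task-group response-total distribution.
#' @param seed Seed.
#' @return List with `ratings` (matrix, 6 items), `group` (factor),
#'   `counts` (numeric, `NA` for control subjects).
#' @export
simulate_ratings <- function(n_task = 45, n_control = 45,
                             item_means_task = c(6.5, 3.0, 4.5, 4.5, 3.7, 5.6),
                             item_means_control = c(3.9, 2.8, 4.0, 4.2, 3.4, 5.1),
                             item_sd_task = 1.8, item_sd_control = 2.0,
                             count_mean = 452.49, count_sd = 155.64,
                             seed = 1) {
  set.seed(seed)
  mk <- function(n, mu, s) {
    m <- matrix(stats::rnorm(n * 6, rep(mu, each = n), s), nrow = n)
    pmin(pmax(m, 0), 10)
  }
  ratings <- rbind(mk(n_task, item_means_task, item_sd_task),
                   mk(n_control, item_means_control, item_sd_control))
  colnames(ratings) <- c("mental", "physical", "temporal", "performance",
                         "effort", "frustration")
  counts <- c(pmax(stats::rnorm(n_task, count_mean, count_sd), 0),
              rep(NA_real_, n_control))
  list(ratings = ratings,
       group = factor(rep(c("task", "control"), c(n_task, n_control)),
                      levels = c("control", "task")),
       counts = counts)
}
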