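heat_test <- function(statistic, df, p_value, method, ...) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), method = method, ...),
            class = "heat_test")
}

#' @export
print.heat_test <- function(x, ...) {
  cat(sprintf("<heat_test> %s\n  statistic %.4g, df %s, p = %.4g\n",
              x$method, x$statistic,
              if (is.null(x$df) || is.na(x$df)) "-" else format(x$df),
              x$p_value))
  invisible(x)
}

#' Pearson chi-squared test of independence
#'
#' Plain Pearson statistic (no continuity correction) with the asymptotic
#' chi-squared p-value, as used for the taxonomic-order and IUCN-status
#' associations with risk tier. Degenerate tables (any expected count zero,
#' i.e. an all-zero row or column) are an error.
#'
#' @param counts A non-negative integer matrix, `table`, or data frame of
#'   counts with at least 2 rows and 2 columns.
#' @return A `heat_test` (statistic, df, p_value); `tidy()` gives a tibble.
#' @export
chi_squared_independence <- function(counts) {
  m <- as.matrix(counts)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("contingency table needs at least 2 rows and 2 columns", call. = FALSE)
  if (any(m < 0) || any(!is.finite(m)))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (sum(m) < 1) stop("empty contingency table", call. = FALSE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    stop("degenerate table: zero expected count (all-zero row or column)",
         call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  heat_test(res$statistic, res$parameter, res$p.value,
            "Pearson chi-squared test of independence",
            expected = expected)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with the chi-squared approximation, comparing a numeric
#' trait (e.g. log range size, envelope width, thermal-maximum delta)
#' across risk tiers. Accepts either a data frame plus column names or a
#' named list of numeric vectors. All-identical values give H = 0, p = 1.
#'
#' @param data A data frame, or a list of numeric group vectors.
#' @param value,group Column names (strings) when `data` is a data frame.
#' @return A `heat_test`.
#' @export
kruskal_wallis <- function(data, value = NULL, group = NULL) {
  g <- grouped_values(data, value, group)
  x <- unlist(g, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    return(heat_test(0, length(g) - 1L, 1,
                     "Kruskal-Wallis rank sum test"))
  }
  grp <- factor(rep(names(g), lengths(g)))
  res <- stats::kruskal.test(x, grp)
  heat_test(res$statistic, res$parameter, res$p.value,
            "Kruskal-Wallis rank sum test")
}

grouped_values <- function(data, value = NULL, group = NULL) {
  if (is.data.frame(data)) {
    stopifnot(is.character(value), is.character(group))
    keep <- is.finite(data[[value]]) & !is.na(data[[group]])
    g <- split(data[[value]][keep], as.character(data[[group]][keep]))
  } else if (is.list(data)) {
    g <- lapply(data, as.numeric)
    if (is.null(names(g))) names(g) <- paste0("g", seq_along(g))
  } else stop("`data` must be a data frame or a list of numeric vectors",
              call. = FALSE)
  if (length(g) < 2L || any(lengths(g) == 0L))
    stop("need at least 2 non-empty groups", call. = FALSE)
  g
}

#' Dunn's post hoc test
#'
#' Pairwise rank-based comparisons following a Kruskal-Wallis test, using
#' the tie-corrected pooled variance
#' `N(N+1)/12 - sum(t^3 - t)/(12(N-1))`; two-sided p-values from the
#' standard normal, optionally adjusted across all pairs.
#'
#' @inheritParams kruskal_wallis
#' @param adjustment `"none"` (default, matching raw reported p-values),
#'   `"holm"` or `"bonferroni"`.
#' @return A tibble with one row per group pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adj`.
#' @export
dunn_posthoc <- function(data, value = NULL, group = NULL,
                         adjustment = c("none", "holm", "bonferroni")) {
  adjustment <- match.arg(adjustment)
  g <- grouped_values(data, value, group)
  x <- unlist(g, use.names = FALSE)
  grp <- rep(names(g), lengths(g))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, grp, mean)
  n <- tapply(r, grp, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(g), 2L)
  out <- purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    se <- sqrt(v0 * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    tibble(group1 = a, group2 = b, z = z,
           p_value = 2 * stats::pnorm(-abs(z)))
  }) |> purrr::list_rbind()
  out$p_adj <- stats::p.adjust(out$p_value, method = adjustment)
  out
}

#' Cross-tabulate risk tier against a categorical trait
#'
#' Counts species per trait level x risk tier and computes row-normalised
#' percentages rounded half-away-from-zero to integers (report-table
#' parity). Species missing the trait are listed in a warning and excluded.
#'
#' @param assessments Tibble with `species_id` and `tier` (e.g. from
#'   [classify_risk()] or a transcribed risk table).
#' @param traits Tibble with `species_id` and the trait column.
#' @param trait Name (string) of the categorical trait column in `traits`.
#' @return An object of class `risk_crosstab`: `counts` (matrix, trait
#'   levels x tiers), `percent` (row percentages, integers) and `table`
#'   (tidy tibble).
#' @export
risk_crosstab <- function(assessments, traits, trait) {
  stopifnot(all(c("species_id", "tier") %in% names(assessments)),
            all(c("species_id", trait) %in% names(traits)))
  d <- dplyr::left_join(assessments[, c("species_id", "tier")],
                        traits[, c("species_id", trait)],
                        by = "species_id")
  miss <- d$species_id[is.na(d[[trait]])]
  if (length(miss)) {
    warning("species missing trait `", trait, "`: ",
            paste(miss, collapse = ", "), " - excluded", call. = FALSE)
    d <- d[!is.na(d[[trait]]), ]
  }
  tier <- factor(as.character(d$tier), levels = risk_levels)
  counts <- table(d[[trait]], tier)
  counts <- unclass(counts)[, risk_levels, drop = FALSE]
  percent <- round_half_up(100 * counts / rowSums(counts))
  tab <- as_tibble(as.data.frame.table(counts, responseName = "n_species"))
  names(tab) <- c(trait, "tier", "n_species")
  tab$pct_within_level <- as.vector(percent[cbind(as.character(tab[[trait]]),
                                                  as.character(tab$tier))])
  structure(list(counts = counts, percent = percent, table = tab,
                 trait = trait),
            class = "risk_crosstab")
}

#' @export
print.risk_crosstab <- function(x, ...) {
  cat("<risk_crosstab> tier by", x$trait, "\ncounts:\n")
  print(x$counts)
  cat("row percentages:\n")
  print(x$percent)
  invisible(x)
}

#' Literature-tally summary across risk tiers
#'
#' Per-tier mean and median study counts plus a Kruskal-Wallis test for a
#' research bias across tiers (are high-risk species less studied?).
#'
#' @param study_counts Tibble with `species_id` and `n_studies`.
#' @param assessments Tibble with `species_id` and `tier` covering every
#'   species in `study_counts`.
#' @return List with `summary` (tibble: tier, n_species, mean/median
#'   studies) and `test` (`heat_test`).
#' @export
review_tally <- function(study_counts, assessments) {
  stopifnot(all(c("species_id", "n_studies") %in% names(study_counts)),
            all(c("species_id", "tier") %in% names(assessments)))
  if (any(study_counts$n_studies < 0)) stop("negative study count", call. = FALSE)
  d <- dplyr::left_join(study_counts, assessments[, c("species_id", "tier")],
                        by = "species_id")
  if (any(is.na(d$tier)))
    stop("no risk tier for species: ",
         paste(d$species_id[is.na(d$tier)], collapse = ", "), call. = FALSE)
  d$tier <- factor(as.character(d$tier), levels = risk_levels)
  summary <- d |>
    dplyr::group_by(tier) |>
    dplyr::summarise(n_species = dplyr::n(),
                     mean_studies = mean(n_studies),
                     median_studies = stats::median(n_studies),
                     .groups = "drop")
  test <- if (dplyr::n_distinct(d$tier) >= 2L)
    kruskal_wallis(d, "n_studies", "tier") else NULL
  list(summary = summary, test = test)
}
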