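#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability (minimum-likelihood) convention: with margins fixed, the
#' two-sided p-value is the sum of hypergeometric probabilities of all tables
#' whose point probability does not exceed that of the observed table, with a
#' relative slack of 1e-7 to absorb floating-point ties. Probabilities are
#' accumulated in log space. A table with a zero margin carries no
#' information about association and returns the degenerate p = 1 with a
#' warning.
#'
#' @param tab A 2x2 matrix of non-negative counts (by convention rows =
#'   groups, columns = feature present/absent), or the four counts `a, b, c,
#'   d` in row-major order.
#' @param b,c,d Optional remaining cells when `tab` is given as the scalar
#'   `a`.
#' @return A `msimut_test` list: `method`, `statistic` (`NA` for Fisher),
#'   `p_value`, `table`.
#' @examples
#' fisher_two_sided(matrix(c(8, 21, 3, 110), 2, byrow = TRUE))$p_value
#' @export
fisher_two_sided <- function(tab, b = NULL, c = NULL, d = NULL) {
  tab <- as_2x2(tab, b, c, d)
  a <- tab[1, 1]
  m1 <- sum(tab[1, ])                       # row 1 margin (drawn)
  col1 <- sum(tab[, 1])                     # column 1 margin (white)
  col2 <- sum(tab[, 2])
  if (m1 == 0 || sum(tab[2, ]) == 0 || col1 == 0 || col2 == 0) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(new_test("fisher_two_sided", NA_real_, 1, tab))
  }
  support <- max(0, m1 - col2):min(m1, col1)
  logd <- stats::dhyper(support, col1, col2, m1, log = TRUE)
  log_obs <- stats::dhyper(a, col1, col2, m1, log = TRUE)
  sel <- logd <= log_obs + log1p(1e-7)
  p <- min(1, sum(exp(logd[sel])))
  new_test("fisher_two_sided", NA_real_, p, tab)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson statistic on 1 degree of freedom with upper-tail p-value; the
#' Yates continuity correction is off by default and configurable. A table
#' with a zero margin (hence a zero expected cell) returns the degenerate
#' p = 1 with a warning.
#'
#' @inheritParams fisher_two_sided
#' @param correct Apply the Yates continuity correction.
#' @return A `msimut_test` list with the Pearson `statistic` and `p_value`.
#' @export
chi_square_2x2 <- function(tab, b = NULL, c = NULL, d = NULL,
                           correct = FALSE) {
  tab <- as_2x2(tab, b, c, d)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    warning("degenerate 2x2 table (zero expected cell); p = 1")
    return(new_test("chi_square", NA_real_, 1, tab))
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  new_test("chi_square", unname(res$statistic), unname(res$p.value), tab)
}

#' Two-sample Student t-test on burden vectors
#'
#' Two-sided pooled-variance Student t by default; set `var_equal = FALSE`
#' for the Welch form. Degenerate zero-variance input is resolved by
#' convention: equal means give p = 1, unequal means p = 0 (the group
#' difference is certain relative to zero within-group spread), each with a
#' warning.
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @param var_equal Pool the variances (classical Student t).
#' @return A `msimut_test` list with the `statistic` and `p_value`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      warning("zero variance in both samples with equal means; p = 1")
      return(new_test("t_student", 0, 1, NULL))
    }
    warning("zero variance in both samples with unequal means; p = 0")
    return(new_test("t_student", Inf * sign(mean(x) - mean(y)), 0, NULL))
  }
  res <- stats::t.test(x, y, var.equal = var_equal)
  new_test("t_student", unname(res$statistic), unname(res$p.value), NULL)
}

as_2x2 <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b)) tab <- matrix(c(tab, b, c, d), 2, 2, byrow = TRUE)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    stop("expected a 2x2 table of non-negative counts", call. = FALSE)
  }
  storage.mode(tab) <- "double"
  tab
}

new_test <- function(method, statistic, p_value, tab) {
  structure(list(method = method, statistic = statistic,
                 p_value = p_value, table = tab),
            class = "msimut_test")
}

#' @export
print.msimut_test <- function(x, ...) {
  cat("<msimut_test> ", x$method,
      if (!is.na(x$statistic)) sprintf(" statistic=%.4g", x$statistic),
      sprintf(" p=%.4g", x$p_value), "\n", sep = "")
  invisible(x)
}

#' Gene and gene-set mutation frequencies by MSI group
#'
#' For each named gene or gene set, counts the tumors carrying at least one
#' mutation in the set per MSI group (a tumor counts once per set regardless
#' of mutation multiplicity), builds the 2x2 table (rows MSI-H/MSS, columns
#' mutated/not) and attaches the two-sided Fisher exact p-value alongside
#' the uncorrected chi-square p. No multiple-testing correction is applied.
#' Percentages are displayed rounded to integers.
#'
#' @param x An `msi_cohort` containing both MSS and MSI-H tumors.
#' @param gene_sets Named list of gene-symbol vectors (default
#'   [default_gene_sets()], the profiled genes plus the mTOR-pathway and RTK
#'   family sets).
#' @return Tibble with one row per set: `name`, `mss_mutated`, `mss_total`,
#'   `mss_pct`, `msih_mutated`, `msih_total`, `msih_pct`, `table` (list
#'   column of 2x2 matrices), `p_fisher`, `p_chisq`, `p_value` (Fisher).
#' @export
gene_frequency_table <- function(x, gene_sets = default_gene_sets()) {
  stopifnot(inherits(x, "msi_cohort"))
  known <- union(panel_genes(), unique(x$mutations$gene))
  unknown <- setdiff(unique(unlist(gene_sets)), known)
  if (length(unknown) > 0) {
    stop("config error: unknown gene symbol(s) in gene_sets: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  status <- x$samples$msi_status
  if (!all(c("MSS", "MSI_H") %in% status)) {
    stop("evaluation error: both MSS and MSI_H tumors are required",
         call. = FALSE)
  }
  n_mss <- sum(status == "MSS")
  n_msih <- sum(status == "MSI_H")
  mut_status <- status[match(x$mutations$tumor_id, x$samples$tumor_id)]

  rows <- lapply(names(gene_sets), function(nm) {
    genes <- gene_sets[[nm]]
    in_set <- x$mutations$gene %in% genes
    mss_mut <- length(unique(x$mutations$tumor_id[in_set &
                                                    mut_status == "MSS"]))
    msih_mut <- length(unique(x$mutations$tumor_id[in_set &
                                                     mut_status == "MSI_H"]))
    tab <- matrix(c(msih_mut, n_msih - msih_mut,
                    mss_mut, n_mss - mss_mut), 2, 2, byrow = TRUE,
                  dimnames = list(c("MSI_H", "MSS"),
                                  c("mutated", "not_mutated")))
    p_f <- withCallingHandlers(fisher_two_sided(tab)$p_value,
                               warning = function(w) invokeRestart("muffleWarning"))
    p_c <- withCallingHandlers(chi_square_2x2(tab)$p_value,
                               warning = function(w) invokeRestart("muffleWarning"))
    tibble::tibble(
      name = nm,
      mss_mutated = mss_mut, mss_total = n_mss,
      mss_pct = round(100 * mss_mut / n_mss),
      msih_mutated = msih_mut, msih_total = n_msih,
      msih_pct = round(100 * msih_mut / n_msih),
      table = list(tab), p_fisher = p_f, p_chisq = p_c, p_value = p_f
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-gene repeat-indel tallies by MSI group
#'
#' For each gene with indel mutations (plus a `Total` row): the
#' mutation-level fraction of indels that involve a repeat region
#' (`repeat_indels / total indels`) and the per-tumor rate of
#' repeat-involving indels (`repeat_indels / group size`). A gene/group with
#' no indels has a not-evaluable ratio (`NA`) and a zero per-tumor rate.
#' A Fisher p-value on the per-tumor repeat-indel 2x2 (tumors with at least
#' one repeat indel in the gene vs not) is attached.
#'
#' @param x An `msi_cohort`.
#' @param annotations Annotated mutation table from
#'   [annotate_cohort_repeats()].
#' @return Tibble with one row per gene plus `Total`: per group,
#'   `*_repeat_indels`, `*_indels`, `*_ratio`, `*_per_tumor`, and `p_value`.
#' @export
indel_repeat_table <- function(x, annotations) {
  stopifnot(inherits(x, "msi_cohort"))
  status <- x$samples$msi_status
  n_mss <- sum(status == "MSS")
  n_msih <- sum(status == "MSI_H")
  ann <- annotations[annotations$variant_class %in%
                       c("deletion", "insertion_duplication"), , drop = FALSE]
  ann$group <- status[match(ann$tumor_id, x$samples$tumor_id)]
  ann$flagged <- isTRUE_vec(ann$in_repeat)

  genes <- sort(unique(ann$gene))
  tally <- function(sub, n_group) {
    list(rep = sum(sub$flagged), tot = nrow(sub),
         tumors = length(unique(sub$tumor_id[sub$flagged])),
         n = n_group)
  }
  one_row <- function(nm, sub) {
    mss <- tally(sub[sub$group == "MSS", , drop = FALSE], n_mss)
    msih <- tally(sub[sub$group == "MSI_H", , drop = FALSE], n_msih)
    p <- NA_real_
    if (n_mss > 0 && n_msih > 0) {
      tab <- matrix(c(msih$tumors, n_msih - msih$tumors,
                      mss$tumors, n_mss - mss$tumors), 2, 2, byrow = TRUE)
      p <- withCallingHandlers(fisher_two_sided(tab)$p_value,
                               warning = function(w) invokeRestart("muffleWarning"))
    }
    tibble::tibble(
      gene = nm,
      mss_repeat_indels = mss$rep, mss_indels = mss$tot,
      mss_ratio = if (mss$tot > 0) mss$rep / mss$tot else NA_real_,
      mss_per_tumor = if (n_mss > 0) mss$rep / n_mss else NA_real_,
      msih_repeat_indels = msih$rep, msih_indels = msih$tot,
      msih_ratio = if (msih$tot > 0) msih$rep / msih$tot else NA_real_,
      msih_per_tumor = if (n_msih > 0) msih$rep / n_msih else NA_real_,
      p_value = p
    )
  }
  rows <- lapply(genes, function(g) one_row(g, ann[ann$gene == g, ,
                                                   drop = FALSE]))
  rows[[length(rows) + 1]] <- one_row("Total", ann)
  dplyr::bind_rows(rows)
}
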