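#' Build a tumor cohort from mutation and sample tables
#'
#' The cohort is the package's central container: a `samples` table with one
#' row per tumor (including tumors with zero mutations, so burden denominators
#' are tumor counts) and a `mutations` table with one row per somatic call.
#' MSI-Low tumors are collapsed into MSS: the analyses contrast MSS against
#' MSI-H only.
#'
#' @param mutations A data frame with columns `tumor_id`, `gene`, and at least
#'   one of `hgvs_c`/`hgvs_p`; optional `variant_class` (one of
#'   [mutation_classes()]; inferred from `hgvs_c` when absent) and `vaf`
#'   (variant allele fraction in \[0, 1\]).
#' @param samples Optional data frame with column `tumor_id` and optional
#'   `msi_status` (`"MSS"`, `"MSI_H"`/`"MSI-H"`, `"MSI_L"`/`"MSI-L"`,
#'   `"unknown"`), `site`, `stage`, `specimen`, `age`, `sex`. Tumors listed
#'   here but absent from `mutations` are kept with zero mutations. When
#'   `NULL`, samples are derived from the distinct `tumor_id`s in `mutations`.
#' @param name Cohort name.
#' @return An object of class `msi_cohort`: a list with elements `name`,
#'   `samples` and `mutations` (tibbles).
#' @examples
#' muts <- tibble::tibble(
#'   tumor_id = c("T1", "T1", "T2"),
#'   gene = c("TP53", "KRAS", "PTEN"),
#'   hgvs_c = c("c.524G>A", "c.35G>T", "c.800delA"),
#'   hgvs_p = c("p.R175H", "p.G12V", "p.K267Rfs*9"),
#'   variant_class = c("substitution", "substitution", "deletion")
#' )
#' cohort(muts)
#' @export
cohort <- function(mutations, samples = NULL, name = "cohort") {
  mutations <- tibble::as_tibble(mutations)
  required <- c("tumor_id", "gene")
  missing_cols <- setdiff(required, names(mutations))
  if (length(missing_cols) > 0) {
    stop("format error: mutation table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!any(c("hgvs_c", "hgvs_p") %in% names(mutations))) {
    stop("format error: mutation table needs at least one of hgvs_c/hgvs_p",
         call. = FALSE)
  }
  for (col in c("hgvs_c", "hgvs_p")) {
    if (!col %in% names(mutations)) mutations[[col]] <- NA_character_
  }
  if (!"vaf" %in% names(mutations)) mutations[["vaf"]] <- NA_real_
  mutations$tumor_id <- as.character(mutations$tumor_id)
  mutations$gene <- as.character(mutations$gene)
  mutations$hgvs_c <- empty_to_na(as.character(mutations$hgvs_c))
  mutations$hgvs_p <- empty_to_na(as.character(mutations$hgvs_p))

  if (!"variant_class" %in% names(mutations)) {
    mutations$variant_class <- infer_variant_class(mutations$hgvs_c)
  }
  mutations$variant_class <- as.character(mutations$variant_class)

  validate_mutations(mutations)

  if (is.null(samples)) {
    samples <- tibble::tibble(tumor_id = unique(mutations$tumor_id))
  }
  samples <- tibble::as_tibble(samples)
  if (!"tumor_id" %in% names(samples)) {
    stop("format error: samples table lacks tumor_id", call. = FALSE)
  }
  samples$tumor_id <- as.character(samples$tumor_id)
  if (anyDuplicated(samples$tumor_id)) {
    stop("validation error: duplicate tumor ids in samples table: ",
         paste(unique(samples$tumor_id[duplicated(samples$tumor_id)]),
               collapse = ", "), call. = FALSE)
  }
  for (col in c("msi_status", "site", "stage", "specimen", "sex")) {
    if (!col %in% names(samples)) samples[[col]] <- "unknown"
    samples[[col]] <- as.character(samples[[col]])
    samples[[col]][is.na(samples[[col]]) | samples[[col]] == ""] <- "unknown"
  }
  if (!"age" %in% names(samples)) samples$age <- NA_real_
  samples$age <- as.numeric(samples$age)
  samples$msi_status <- normalize_msi_status(samples$msi_status)

  orphan <- setdiff(mutations$tumor_id, samples$tumor_id)
  if (length(orphan) > 0) {
    samples <- dplyr::bind_rows(
      samples,
      tibble::tibble(tumor_id = orphan, msi_status = "unknown",
                     site = "unknown", stage = "unknown",
                     specimen = "unknown", sex = "unknown", age = NA_real_)
    )
  }

  structure(list(name = name, samples = samples, mutations = mutations),
            class = "msi_cohort")
}

empty_to_na <- function(x) {
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  x
}

# MSI-Low is collapsed into MSS; only MSS vs MSI-H is contrasted.
normalize_msi_status <- function(x) {
  x <- gsub("-", "_", toupper(trimws(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("MSS", "MSI_L", "MSI_LOW", "MSIL")] <- "MSS"
  out[x %in% c("MSI_H", "MSIH", "MSI_HIGH")] <- "MSI_H"
  out
}

# Map an HGVS c. string to a variant class; splice-site (intronic-offset)
# notation is classed directly, everything else through the parser.
infer_variant_class <- function(hgvs_c) {
  vapply(hgvs_c, function(h) {
    if (is.na(h)) return(NA_character_)
    if (grepl("^c\\.[-*0-9_+]*[+-]\\d+", h)) return("splice")
    ch <- tryCatch(parse_hgvs_c(h), error = function(e) NULL)
    if (is.null(ch)) return(NA_character_)
    switch(ch$kind,
           sub = "substitution",
           del = "deletion",
           dup = "insertion_duplication",
           ins = "insertion_duplication",
           delins = "substitution")
  }, character(1), USE.NAMES = FALSE)
}

validate_mutations <- function(mutations) {
  no_hgvs <- is.na(mutations$hgvs_c) & is.na(mutations$hgvs_p)
  if (any(no_hgvs)) {
    stop("validation error: row(s) ", paste(which(no_hgvs), collapse = ", "),
         " have neither hgvs_c nor hgvs_p", call. = FALSE)
  }
  bad_class <- !is.na(mutations$variant_class) &
    !(mutations$variant_class %in% mutation_classes())
  if (any(bad_class)) {
    stop("validation error: unrecognized variant_class in row(s) ",
         paste(which(bad_class), collapse = ", "), ": ",
         paste(unique(mutations$variant_class[bad_class]), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(mutations$tumor_id, mutations$gene, mutations$hgvs_c, sep = "\r")
  dup <- duplicated(key) & !is.na(mutations$hgvs_c)
  if (any(dup)) {
    offenders <- unique(paste0(mutations$tumor_id[dup], "/",
                               mutations$gene[dup], "/", mutations$hgvs_c[dup]))
    stop("validation error: duplicate (tumor, gene, hgvs_c) rows: ",
         paste(offenders, collapse = "; "), call. = FALSE)
  }
  bad_vaf <- !is.na(mutations$vaf) & (mutations$vaf < 0 | mutations$vaf > 1)
  if (any(bad_vaf)) {
    stop("validation error: vaf outside [0,1] in row(s) ",
         paste(which(bad_vaf), collapse = ", "), call. = FALSE)
  }
  # variant_class must agree with the hgvs_c kind whenever the string parses
  inferred <- infer_variant_class(mutations$hgvs_c)
  clash <- !is.na(inferred) & !is.na(mutations$variant_class) &
    inferred != mutations$variant_class
  if (any(clash)) {
    stop("validation error: variant_class inconsistent with hgvs_c in row(s) ",
         paste(which(clash), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.msi_cohort <- function(x, ...) {
  sizes <- group_sizes(x)
  cat("<msi_cohort> ", x$name, ": ", nrow(x$samples), " tumors (",
      paste(names(sizes), sizes, sep = "=", collapse = ", "), "), ",
      nrow(x$mutations), " mutations\n", sep = "")
  invisible(x)
}

#' Tumor counts per MSI group
#'
#' @param x An `msi_cohort`.
#' @return Named integer vector over the statuses present.
#' @export
group_sizes <- function(x) {
  stopifnot(inherits(x, "msi_cohort"))
  tab <- table(x$samples$msi_status)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Read a MAF-like tab-separated mutation table
#'
#' Expects a header row with columns `tumor_id`, `gene` and at least one of
#' `hgvs_c`/`hgvs_p`; optional `variant_class` and `vaf`. Rows whose
#' `variant_class` is unrecognized or that carry no HGVS description are
#' rejected and reported via a message and the `"rejected"` attribute of the
#' result — never silently dropped. An optional samples side-table carries
#' MSI status and clinical covariates and lets zero-mutation tumors be
#' represented.
#'
#' @param path Path to the mutation TSV.
#' @param samples_path Optional path to a samples TSV (column `tumor_id` plus
#'   optional covariates).
#' @param name Cohort name.
#' @return An `msi_cohort`; rejected rows (if any) are attached as attribute
#'   `"rejected"`.
#' @export
read_mutation_table <- function(path, samples_path = NULL, name = "cohort") {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  raw <- tibble::as_tibble(raw)
  required <- c("tumor_id", "gene")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0 || !any(c("hgvs_c", "hgvs_p") %in% names(raw))) {
    stop("format error: ", path, " lacks required column(s): ",
         paste(c(missing_cols,
                 if (!any(c("hgvs_c", "hgvs_p") %in% names(raw)))
                   "hgvs_c/hgvs_p"), collapse = ", "), call. = FALSE)
  }
  for (col in c("hgvs_c", "hgvs_p")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  }
  if ("vaf" %in% names(raw)) raw$vaf <- as.numeric(raw$vaf)

  bad <- (is.na(raw$hgvs_c) & is.na(raw$hgvs_p)) |
    is.na(raw$tumor_id) | is.na(raw$gene)
  if ("variant_class" %in% names(raw)) {
    bad <- bad | (!is.na(raw$variant_class) &
                    !(raw$variant_class %in% mutation_classes()))
  }
  rejected <- raw[bad, , drop = FALSE]
  if (nrow(rejected) > 0) {
    message("read_mutation_table: rejected ", nrow(rejected),
            " unparseable row(s) at line(s) ",
            paste(which(bad), collapse = ", "))
  }
  raw <- raw[!bad, , drop = FALSE]

  samples <- NULL
  if (!is.null(samples_path)) {
    samples <- utils::read.delim(samples_path, sep = "\t",
                                 stringsAsFactors = FALSE,
                                 check.names = FALSE,
                                 na.strings = c("NA", ""))
  }
  out <- cohort(raw, samples = samples, name = name)
  attr(out, "rejected") <- tibble::as_tibble(rejected)
  out
}

#' Write a cohort back to MAF-like TSV (plus samples side-table)
#'
#' Inverse of [read_mutation_table()]: a write/read round trip preserves every
#' `(tumor_id, gene, hgvs_c, variant_class)` tuple, including zero-mutation
#' tumors via the samples table.
#'
#' @param x An `msi_cohort`.
#' @param path Output mutation TSV path.
#' @param samples_path Optional output samples TSV path.
#' @return Invisibly, `x`.
#' @export
write_mutation_table <- function(x, path, samples_path = NULL) {
  stopifnot(inherits(x, "msi_cohort"))
  utils::write.table(x$mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(samples_path)) {
    utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(x)
}

#' Read a minimal annotated VCF into a cohort
#'
#' Reads a VCF 4.x whose INFO field carries gene and HGVS annotations under
#' configurable keys. Each sample column is a tumor; a record is assigned to
#' every sample whose genotype contains a non-reference allele (full
#' multi-sample genotype semantics are out of scope). Records with symbolic
#' ALT alleles (e.g. `<DEL>`) are skipped with a warning.
#'
#' @param path Path to the VCF.
#' @param annotation_fields Named list mapping the INFO keys used for
#'   `gene`, `hgvs_c`, `hgvs_p` and (optionally) `variant_class`.
#' @param name Cohort name.
#' @return An `msi_cohort` (empty if the VCF has no sample columns).
#' @export
read_minimal_vcf <- function(path,
                             annotation_fields = list(gene = "GENE",
                                                      hgvs_c = "HGVSC",
                                                      hgvs_p = "HGVSP",
                                                      variant_class = "CLASS"),
                             name = "cohort") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_minimal_vcf requires the vcfR package", call. = FALSE)
  }
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt
  sample_ids <- if (is.null(gt) || ncol(gt) < 2) character(0) else
    colnames(gt)[-1]
  empty <- cohort(
    tibble::tibble(tumor_id = character(), gene = character(),
                   hgvs_c = character(), hgvs_p = character(),
                   variant_class = character()),
    samples = tibble::tibble(tumor_id = sample_ids),
    name = name
  )
  if (nrow(fix) == 0 || length(sample_ids) == 0) return(empty)

  symbolic <- grepl("^<.*>$", fix$ALT) | grepl("\\[|\\]", fix$ALT)
  if (any(symbolic)) {
    warning("read_minimal_vcf: skipped ", sum(symbolic),
            " record(s) with symbolic ALT alleles")
  }
  keep <- which(!symbolic)

  get_info <- function(key) {
    if (is.null(key)) return(rep(NA_character_, nrow(fix)))
    vcfR::extract.info(vcf, element = key)
  }
  gene <- get_info(annotation_fields$gene)
  if (all(is.na(gene[keep]))) {
    stop("format error: INFO field '", annotation_fields$gene,
         "' absent from ", path, call. = FALSE)
  }
  hgvs_c <- get_info(annotation_fields$hgvs_c)
  hgvs_p <- get_info(annotation_fields$hgvs_p)
  vclass <- get_info(annotation_fields$variant_class)

  rows <- list()
  for (i in keep) {
    gts <- gt[i, -1, drop = TRUE]
    alleles <- sub(":.*", "", gts)
    carrier <- grepl("[1-9]", alleles)
    for (s in sample_ids[carrier]) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        tumor_id = s, gene = gene[i], hgvs_c = hgvs_c[i], hgvs_p = hgvs_p[i],
        variant_class = if (all(is.na(vclass))) NA_character_ else vclass[i]
      )
    }
  }
  if (length(rows) == 0) return(empty)
  muts <- dplyr::bind_rows(rows)
  if (all(is.na(muts$variant_class))) muts$variant_class <- NULL
  cohort(muts, samples = tibble::tibble(tumor_id = sample_ids), name = name)
}

#' Cohort demography summary
#'
#' Per-MSI-group sample size, median age and range, and sex / primary-tumor
#' site / stage / specimen-type counts with percentages. Tumors with an
#' unknown level of a covariate are reported in a separate row and excluded
#' from that covariate's percentages and test denominator only. When both
#' groups are present, a two-sided association p-value is attached per
#' covariate (Fisher exact for 2-level factors, chi-square otherwise; Student
#' t for age); a covariate with all levels unknown is marked not evaluable.
#'
#' @param x An `msi_cohort`.
#' @param path Optional TSV output path.
#' @return A tibble with columns `section`, `level`, `mss`, `msih`,
#'   `mss_pct`, `msih_pct`, `p_value`, `note`.
#' @export
write_cohort_summary <- function(x, path = NULL) {
  stopifnot(inherits(x, "msi_cohort"))
  if (nrow(x$samples) == 0) stop("cohort is empty", call. = FALSE)
  s <- x$samples
  mss <- s[s$msi_status == "MSS", , drop = FALSE]
  msih <- s[s$msi_status == "MSI_H", , drop = FALSE]
  both <- nrow(mss) > 0 && nrow(msih) > 0

  rows <- list(tibble::tibble(
    section = "n", level = "tumors", mss = nrow(mss), msih = nrow(msih),
    mss_pct = NA_real_, msih_pct = NA_real_, p_value = NA_real_, note = ""
  ))

  age_row <- tibble::tibble(
    section = "age", level = "median (range)",
    mss = stats::median(mss$age, na.rm = TRUE),
    msih = stats::median(msih$age, na.rm = TRUE),
    mss_pct = NA_real_, msih_pct = NA_real_, p_value = NA_real_, note = ""
  )
  if (both && sum(!is.na(mss$age)) >= 2 && sum(!is.na(msih$age)) >= 2) {
    age_row$p_value <- two_sample_t(mss$age[!is.na(mss$age)],
                                    msih$age[!is.na(msih$age)])$p_value
  }
  rows[[length(rows) + 1]] <- age_row

  for (covar in c("sex", "site", "stage", "specimen")) {
    a <- mss[[covar]]
    b <- msih[[covar]]
    known_a <- a[a != "unknown"]
    known_b <- b[b != "unknown"]
    levels_known <- sort(unique(c(known_a, known_b)))
    if (length(levels_known) == 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        section = covar, level = "(all unknown)",
        mss = length(a), msih = length(b),
        mss_pct = NA_real_, msih_pct = NA_real_, p_value = NA_real_,
        note = "not evaluable"
      )
      next
    }
    p <- NA_real_
    if (both && length(levels_known) >= 2 &&
        length(known_a) > 0 && length(known_b) > 0) {
      tab <- rbind(table(factor(known_b, levels = levels_known)),
                   table(factor(known_a, levels = levels_known)))
      p <- if (length(levels_known) == 2) {
        fisher_two_sided(tab)$p_value
      } else {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      }
    }
    for (lv in levels_known) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        section = covar, level = lv,
        mss = sum(known_a == lv), msih = sum(known_b == lv),
        mss_pct = round(100 * sum(known_a == lv) / max(1, length(known_a))),
        msih_pct = round(100 * sum(known_b == lv) / max(1, length(known_b))),
        p_value = if (lv == levels_known[1]) p else NA_real_, note = ""
      )
    }
    n_unk_a <- sum(a == "unknown")
    n_unk_b <- sum(b == "unknown")
    if (n_unk_a + n_unk_b > 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        section = covar, level = "unknown", mss = n_unk_a, msih = n_unk_b,
        mss_pct = NA_real_, msih_pct = NA_real_, p_value = NA_real_,
        note = "excluded from denominators"
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  out
}
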