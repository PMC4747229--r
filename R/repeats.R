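#' Annotate an indel for homopolymer / short-tandem-repeat context
#'
#' Determines whether a deletion, duplication or insertion sits in a tandem
#' repeat of the reference coding sequence — the signature of replication
#' slippage under defective mismatch repair. The indel is "in repeat" when
#' its inserted/deleted sequence equals `k >= 1` copies of a unit of 1–6 bp
#' and the maximal reference run of tandem copies of that unit containing
#' (for deletions/duplications) or flanking (for insertions) the change has
#' at least 2 copies. The smallest qualifying unit is reported — a `TT`
#' duplication in a `TT` context scores as unit `"T"`, 2 copies — and any
#' larger whole-multiple interpretation is recorded in `notes`. The unit is
#' reported in the phase at which the run starts (its leftmost aligned copy),
#' so a `TACT` deletion from a `(TACT)2` block reports unit `"TACT"`.
#'
#' Because the maximal run is located from the reference, the annotation is
#' identical wherever within the same run the indel is written
#' (left/right-alignment invariance) and is unchanged by sequence flanking
#' the run.
#'
#' @param change A `coding_change` from [parse_hgvs_c()]; must be of kind
#'   `del`, `dup` or `ins` (substitutions have no slippage context and are a
#'   contract error).
#' @param coding_sequence Reference coding sequence (character scalar or
#'   `Biostrings::DNAString`); HGVS coordinates index into it 1-based.
#' @return An object of class `repeat_annotation`: list with `in_repeat`,
#'   `unit` (`""` when not in repeat), `copies` (reference copy count),
#'   `run_start`, `run_end` (coding coordinates of the run) and `notes`.
#' @examples
#' ref <- paste0(strrep("CGT", 10), "AAAAAA", strrep("CGT", 10))
#' annotate_repeat(parse_hgvs_c("c.36delA"), ref)
#' @export
annotate_repeat <- function(change, coding_sequence) {
  if (!inherits(change, "coding_change")) {
    stop("contract error: change must be a coding_change", call. = FALSE)
  }
  if (change$kind %in% c("sub", "delins")) {
    stop("contract error: annotate_repeat is defined for del/dup/ins, not ",
         change$kind, call. = FALSE)
  }
  seq <- toupper(as.character(coding_sequence))
  n <- nchar(seq)
  a <- change$start
  b <- change$end

  if (change$kind %in% c("del", "dup")) {
    if (a < 1 || b > n) {
      stop("contract error: change coordinates ", a, "_", b,
           " fall outside the ", n, " nt reference", call. = FALSE)
    }
    ref_seg <- substr(seq, a, b)
    stated <- if (change$kind == "del") change$ref_seq else change$alt_seq
    if (nzchar(stated) && !identical(stated, ref_seg)) {
      stop("reference-mismatch error: HGVS states ", stated,
           " but reference has ", ref_seg, " at ", a, "_", b, call. = FALSE)
    }
    s <- ref_seg
  } else {                                       # ins between a and b = a + 1
    if (a < 1 || b > n) {
      stop("contract error: insertion point ", a, "_", b,
           " falls outside the ", n, " nt reference", call. = FALSE)
    }
    s <- change$alt_seq
  }

  best <- NULL
  notes <- character(0)
  for (L in seq_len(min(nchar(s), 6L))) {
    if (nchar(s) %% L != 0) next
    u <- substr(s, 1, L)
    if (strrep(u, nchar(s) / L) != s) next
    cand <- if (change$kind == "ins") {
      ins_run(seq, u, point = a)
    } else {
      span_run(seq, u, a, b)
    }
    if (is.null(best)) {
      best <- cand
    } else {
      notes <- c(notes, sprintf("alt unit %s: %d reference copies",
                                cand$unit, cand$copies))
    }
  }
  if (is.null(best)) {               # no unit decomposition (ins-only corner)
    best <- list(in_repeat = FALSE, unit = "", copies = 0L,
                 run_start = NA_integer_, run_end = NA_integer_)
  }
  if (best$in_repeat) {
    canon <- min_rotation(best$unit)
    if (canon != best$unit) {
      notes <- c(notes, sprintf("canonical rotation: %s", canon))
    }
  } else {
    best$unit <- ""
  }
  structure(c(best, list(notes = paste(notes, collapse = "; "))),
            class = "repeat_annotation")
}

# Maximal aligned run of unit u containing the span a..b (the span itself is
# whole copies of u in the reference).
span_run <- function(seq, u, a, b) {
  L <- nchar(u)
  n <- nchar(seq)
  left <- a
  while (left - L >= 1 && substr(seq, left - L, left - 1) == u) left <- left - L
  right <- b
  while (right + L <= n && substr(seq, right + 1, right + L) == u) {
    right <- right + L
  }
  copies <- as.integer((right - left + 1) / L)
  list(in_repeat = copies >= 2L, unit = u, copies = copies,
       run_start = as.integer(left), run_end = as.integer(right))
}

# Reference copies of u flanking an insertion point (between `point` and
# `point + 1`); the inserted copies themselves are not in the reference.
ins_run <- function(seq, u, point) {
  L <- nchar(u)
  n <- nchar(seq)
  right <- 0L
  pos <- point + 1L
  while (pos + L - 1 <= n && substr(seq, pos, pos + L - 1) == u) {
    right <- right + 1L
    pos <- pos + L
  }
  left <- 0L
  pos <- point
  while (pos - L + 1 >= 1 && substr(seq, pos - L + 1, pos) == u) {
    left <- left + 1L
    pos <- pos - L
  }
  copies <- left + right
  list(in_repeat = copies >= 2L, unit = u, copies = copies,
       run_start = if (copies > 0) as.integer(point - left * L + 1)
                   else NA_integer_,
       run_end = if (copies > 0) as.integer(point + right * L)
                 else NA_integer_)
}

# Lexicographically minimal rotation of a unit (identity key across phases).
min_rotation <- function(u) {
  L <- nchar(u)
  if (L <= 1) return(u)
  rots <- vapply(seq_len(L), function(i) {
    paste0(substr(u, i, L), substr(u, 1, i - 1))
  }, character(1))
  min(rots)
}

#' @export
print.repeat_annotation <- function(x, ...) {
  if (x$in_repeat) {
    cat("<repeat_annotation> in repeat: (", x$unit, ")", x$copies,
        " at ", x$run_start, "-", x$run_end, "\n", sep = "")
  } else {
    cat("<repeat_annotation> not in a repeat (", x$copies,
        " reference cop", if (x$copies == 1) "y" else "ies", ")\n", sep = "")
  }
  invisible(x)
}

#' Annotate every indel in a cohort for repeat context
#'
#' Applies [annotate_repeat()] to each deletion / insertion-duplication call
#' whose gene has a reference coding sequence, appending `in_repeat`, `unit`
#' and `copies` columns to the mutation table. Non-indel rows, rows whose
#' HGVS string does not parse, and genes without a reference get `NA`
#' annotations (and a note in the `annotation_note` column) rather than being
#' dropped.
#'
#' @param x An `msi_cohort`.
#' @param references Named character vector (or `DNAStringSet`) of coding
#'   sequences keyed by gene symbol, e.g. from [reference_fixtures()].
#' @return The mutation tibble with columns `in_repeat` (logical), `unit`,
#'   `copies`, `annotation_note` appended.
#' @export
annotate_cohort_repeats <- function(x, references) {
  stopifnot(inherits(x, "msi_cohort"))
  refs <- vapply(as.list(references), as.character, character(1))
  muts <- x$mutations
  n <- nrow(muts)
  in_repeat <- rep(NA, n)
  unit <- rep(NA_character_, n)
  copies <- rep(NA_integer_, n)
  note <- rep("", n)
  indel <- muts$variant_class %in% c("deletion", "insertion_duplication")
  for (i in seq_len(n)) {
    if (!isTRUE(indel[i])) {
      note[i] <- "not an indel"
      next
    }
    if (is.na(muts$hgvs_c[i])) {
      note[i] <- "no hgvs_c"
      next
    }
    if (!muts$gene[i] %in% names(refs)) {
      note[i] <- "no reference sequence"
      next
    }
    ann <- tryCatch(
      annotate_repeat(parse_hgvs_c(muts$hgvs_c[i]), refs[[muts$gene[i]]]),
      error = function(e) NULL
    )
    if (is.null(ann)) {
      note[i] <- "annotation failed"
      next
    }
    in_repeat[i] <- ann$in_repeat
    unit[i] <- ann$unit
    copies[i] <- ann$copies
    note[i] <- ann$notes
  }
  muts$in_repeat <- in_repeat
  muts$unit <- unit
  muts$copies <- copies
  muts$annotation_note <- note
  muts
}
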