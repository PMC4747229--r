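#' Parse an HGVS coding-DNA description
#'
#' Parses the HGVS c. subset arising from hotspot-panel calls: substitutions
#' (`c.697C>T`), deletions (`c.800delA`, `c.954_957del`), duplications
#' (`c.531_532dupTT`), insertions (`c.100_101insAG`) and deletion-insertions
#' (`c.100_102delinsTT`). Coordinates are 1-based inclusive coding positions,
#' as in the notation itself. Intronic offsets (`c.100+2T>C`), UTR positions
#' (`c.-12`, `c.*35`) and inversions are rejected explicitly: they cannot be
#' placed on a coding sequence.
#'
#' @param text An HGVS string beginning `"c."`.
#' @return An object of class `coding_change`: list with `kind` (one of
#'   `"sub"`, `"del"`, `"dup"`, `"ins"`, `"delins"`), `start`, `end`
#'   (1-based, inclusive), `ref_seq` and `alt_seq` (possibly `""`).
#' @examples
#' parse_hgvs_c("c.800delA")
#' parse_hgvs_c("c.531_532dupTT")
#' @export
parse_hgvs_c <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    stop("parse error: HGVS input must be a single string", call. = FALSE)
  }
  text <- trimws(text)
  if (!startsWith(text, "c.")) {
    stop("parse error: '", text, "' does not begin with 'c.'", call. = FALSE)
  }
  body <- substr(text, 3, nchar(text))
  if (grepl("[+-]", body) || grepl("\\*", body)) {
    stop("parse error: intronic/UTR position in '", text,
         "' is not supported", call. = FALSE)
  }
  if (grepl("inv", body)) {
    stop("parse error: inversion in '", text, "' is not supported",
         call. = FALSE)
  }

  new_change <- function(kind, start, end, ref = "", alt = "") {
    start <- as.integer(start)
    end <- as.integer(end)
    if (start > end) {
      stop("parse error: start > end in '", text, "'", call. = FALSE)
    }
    structure(list(kind = kind, start = start, end = end,
                   ref_seq = ref, alt_seq = alt),
              class = "coding_change")
  }

  m <- regmatches(body, regexec("^(\\d+)([ACGT])>([ACGT])$", body))[[1]]
  if (length(m) > 0) {
    return(new_change("sub", m[2], m[2], ref = m[3], alt = m[4]))
  }
  m <- regmatches(body,
                  regexec("^(\\d+)(?:_(\\d+))?delins([ACGT]+)$", body))[[1]]
  if (length(m) > 0) {
    end <- if (m[3] == "") m[2] else m[3]
    return(new_change("delins", m[2], end, alt = m[4]))
  }
  m <- regmatches(body, regexec("^(\\d+)(?:_(\\d+))?del([ACGT]*)$", body))[[1]]
  if (length(m) > 0) {
    end <- if (m[3] == "") m[2] else m[3]
    ch <- new_change("del", m[2], end, ref = m[4])
    check_span_seq(ch, ch$ref_seq, text)
    return(ch)
  }
  m <- regmatches(body, regexec("^(\\d+)(?:_(\\d+))?dup([ACGT]*)$", body))[[1]]
  if (length(m) > 0) {
    end <- if (m[3] == "") m[2] else m[3]
    ch <- new_change("dup", m[2], end, alt = m[4])
    check_span_seq(ch, ch$alt_seq, text)
    return(ch)
  }
  m <- regmatches(body, regexec("^(\\d+)_(\\d+)ins([ACGT]+)$", body))[[1]]
  if (length(m) > 0) {
    if (as.integer(m[3]) != as.integer(m[2]) + 1L) {
      stop("parse error: insertion positions in '", text,
           "' must be adjacent", call. = FALSE)
    }
    return(new_change("ins", m[2], m[3], alt = m[4]))
  }
  stop("parse error: unrecognized HGVS token '", body, "' in '", text, "'",
       call. = FALSE)
}

check_span_seq <- function(ch, seq, text) {
  if (nzchar(seq) && nchar(seq) != ch$end - ch$start + 1L) {
    stop("parse error: sequence length in '", text,
         "' disagrees with the coordinate span", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.coding_change <- function(x, ...) {
  cat("<coding_change> ", x$kind, " ", x$start,
      if (x$end != x$start) paste0("_", x$end) else "",
      if (nzchar(x$ref_seq)) paste0(" ref=", x$ref_seq) else "",
      if (nzchar(x$alt_seq)) paste0(" alt=", x$alt_seq) else "", "\n", sep = "")
  invisible(x)
}

#' Count foreign amino acids encoded by a protein HGVS description
#'
#' Frameshift notation `fs*N` gives the number of out-of-frame ("foreign")
#' residues translated before the new stop codon — the candidate neoepitope
#' length. Nonsense (`Ter` or `*`) and missense changes contribute no foreign
#' residues and return 0. A frameshift whose extent is not annotated
#' (`fs` or `fs*?`) returns `NA` — unknown, deliberately distinct from 0.
#'
#' @param hgvs_p Character vector of protein HGVS strings (e.g.
#'   `"p.K267Rfs*9"`).
#' @return Integer vector: foreign-residue counts, `NA` where unknown.
#' @examples
#' foreign_peptide_length(c("p.N323Mfs*21", "p.R233Ter", "p.G12V"))
#' @export
foreign_peptide_length <- function(hgvs_p) {
  vapply(hgvs_p, function(p) {
    if (is.na(p)) return(NA_integer_)
    p <- trimws(p)
    if (!startsWith(p, "p.")) {
      stop("parse error: '", p, "' does not begin with 'p.'", call. = FALSE)
    }
    body <- substr(p, 3, nchar(p))
    m <- regmatches(body, regexec("fs\\*(\\d+)$", body))[[1]]
    if (length(m) > 0) return(as.integer(m[2]))
    if (grepl("fs(\\*\\?)?$", body)) return(NA_integer_)
    if (grepl("(Ter|\\*)$", body)) return(0L)
    if (grepl("^[A-Z][a-z]{0,2}\\d+[A-Z][a-z]{0,2}$", body) || body == "=") {
      return(0L)
    }
    stop("parse error: unrecognized protein HGVS '", p, "'", call. = FALSE)
  }, integer(1), USE.NAMES = FALSE)
}

#' Expected frameshift neoepitope length under an i.i.d. codon model
#'
#' After a frameshift, each out-of-frame codon is a stop with probability
#' `p_stop` (3 of the 64 codons under a uniform model). The number of codons
#' read until and including the first stop is geometric with mean
#' `1 / p_stop`; at the default `p_stop = 3/64` this is 64/3, about 21
#' residues of foreign sequence. The alternative convention `(1 - p) / p`
#' counts only the codons before the stop (mean about 20.3); `1 / p` is used
#' here because the ~21-residue expectation quoted for frameshift
#' neoepitopes corresponds to including the terminating codon.
#'
#' @param p_stop Per-codon stop probability, in (0, 1].
#' @return Expected codon count (`1 / p_stop`).
#' @examples
#' expected_foreign_peptide_length()      # 64/3 ~ 21.3
#' expected_foreign_peptide_length(1/2)   # 2
#' @export
expected_foreign_peptide_length <- function(p_stop = 3 / 64) {
  if (!is.numeric(p_stop) || length(p_stop) != 1 || is.na(p_stop) ||
      p_stop <= 0 || p_stop > 1) {
    stop("domain error: p_stop must lie in (0, 1]", call. = FALSE)
  }
  1 / p_stop
}
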