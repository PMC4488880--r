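#' Conservation profiles
#'
#' A conservation profile is a tibble with one row per site of a protein
#' sequence: `pos` (1-based position, strictly increasing), `aa` (the
#' query residue, `NA` when the source file omits it) and `score`, the
#' site-specific substitution rate. The orientation is fixed throughout
#' the package: a lower score means a more conserved site, and scores are
#' never sign-flipped anywhere.
#'
#' @name conservation-profiles
NULL

new_conservation <- function(pos, aa, score, normalized = FALSE,
                             source = NA_character_) {
  out <- tibble(pos = as.integer(pos), aa = aa, score = as.numeric(score))
  structure(out, class = c("conservation_profile", class(as_tibble(out))),
            normalized = normalized, source = source)
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d sites%s\n", nrow(x),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  NextMethod()
  invisible(x)
}

#' Read Rate4Site / ConSurf site scores
#'
#' Reads site-specific substitution rates in the Rate4Site grades dialect
#' (comment lines starting with `#`; data rows `POS SEQ SCORE ...`) or a
#' plain two/three-column table (`pos score` or `pos aa score`). The
#' layout is sniffed per row: when the second field is a single letter it
#' is taken as the query residue and the score is read from the third
#' field. Scores are taken as printed -- no sign flip, lower = more
#' conserved.
#'
#' @param path path to the grades/score file.
#' @param score_column optional 1-based field index of the score, for
#'   dialects whose extra columns precede the rate.
#' @return a conservation profile tibble.
#' @export
parse_rate4site <- function(path, score_column = NULL) {
  if (!file.exists(path)) {
    abort(paste0("conservation file not found: ", path),
          class = "capsidprof_input_error")
  }
  ln <- readLines(path, warn = FALSE)
  raw <- trimws(ln)
  keep <- nzchar(raw) & !startsWith(raw, "#")
  rows <- raw[keep]
  lineno <- which(keep)
  if (length(rows) == 0) {
    abort(paste0("no data rows in '", path, "'"),
          class = "capsidprof_input_error")
  }
  parsed <- lapply(seq_along(rows), function(i) {
    tok <- strsplit(rows[[i]], "\\s+")[[1]]
    pos <- suppressWarnings(as.integer(tok[1]))
    if (is.na(pos)) {
      abort(paste0(path, " line ", lineno[i], ": expected a site index, got '",
                   tok[1], "'"),
            class = "capsidprof_input_error")
    }
    has_aa <- length(tok) >= 2 && grepl("^[A-Za-z]$", tok[2])
    sc_idx <- score_column %||% (if (has_aa) 3L else 2L)
    if (length(tok) < sc_idx) {
      abort(paste0(path, " line ", lineno[i], ": no score field"),
            class = "capsidprof_input_error")
    }
    score <- suppressWarnings(as.numeric(tok[sc_idx]))
    if (is.na(score)) {
      abort(paste0(path, " line ", lineno[i], ": score '", tok[sc_idx],
                   "' is not numeric"),
            class = "capsidprof_input_error")
    }
    list(pos = pos, aa = if (has_aa) toupper(tok[2]) else NA_character_,
         score = score)
  })
  pos <- vapply(parsed, `[[`, 1L, "pos")
  if (any(diff(pos) <= 0)) {
    bad <- which(diff(pos) <= 0)[1]
    abort(paste0(path, ": site positions not strictly increasing at line ",
                 lineno[bad + 1]),
          class = "capsidprof_input_error")
  }
  new_conservation(pos,
                   vapply(parsed, `[[`, "", "aa"),
                   vapply(parsed, `[[`, 1, "score"),
                   source = path)
}

#' Write a conservation profile in the grades dialect
#'
#' Writes `POS SEQ SCORE` rows (17 significant digits, so
#' [parse_rate4site()] recovers the scores exactly) under `#` comment
#' headers.
#'
#' @param cons a conservation profile tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grades <- function(cons, path) {
  aa <- cons$aa
  aa[is.na(aa)] <- "X"
  writeLines(c("# site-specific conservation scores (lower = more conserved)",
               "#POS SEQ SCORE",
               sprintf("%d\t%s\t%.17g", cons$pos, aa, cons$score)),
             path)
  invisible(path)
}

#' Column-entropy conservation scores from an alignment
#'
#' A self-contained stand-in scorer for pipelines without Rate4Site
#' output: for each alignment column where the query has a residue, the
#' score is the Shannon entropy (bits) of the amino-acid frequencies in
#' that column, gaps excluded from the counts. Higher entropy = more
#' variable = less conserved, matching the package-wide orientation.
#' This is NOT a substitute for phylogeny-aware rate inference
#' (Rate4Site/ConSurf): it ignores tree structure and sequence
#' redundancy, and its scores are on a different scale.
#'
#' @param msa path to an aligned FASTA file, or a named list of
#'   equal-length character vectors.
#' @param query identifier of the query sequence in the alignment.
#' @return a conservation profile tibble; positions index the ungapped
#'   query sequence.
#' @export
entropy_conservation <- function(msa, query) {
  seqs <- if (is.character(msa) && length(msa) == 1) {
    if (!file.exists(msa)) {
      abort(paste0("alignment file not found: ", msa),
            class = "capsidprof_input_error")
    }
    lapply(seqinr::read.fasta(msa, seqtype = "AA", as.string = FALSE),
           as.character)
  } else {
    msa
  }
  if (length(seqs) == 0) {
    abort("empty alignment", class = "capsidprof_input_error")
  }
  seqs <- lapply(seqs, toupper)
  lens <- vapply(seqs, length, 1L)
  if (length(unique(lens)) != 1) {
    abort("ragged alignment: sequences have unequal aligned lengths",
          class = "capsidprof_input_error")
  }
  if (!query %in% names(seqs)) {
    abort(paste0("query '", query, "' not in alignment (ids: ",
                 paste(utils::head(names(seqs), 5), collapse = ", "), ")"),
          class = "capsidprof_input_error")
  }
  gap <- c("-", ".")
  q <- seqs[[query]]
  mat <- do.call(rbind, seqs)
  keep_col <- !(q %in% gap)
  cols <- which(keep_col)
  score <- vapply(cols, function(j) {
    col <- mat[, j]
    col <- col[!(col %in% gap)]
    p <- table(col) / length(col)
    -sum(p * log2(p))
  }, 1)
  new_conservation(pos = seq_along(cols), aa = q[cols], score = score,
                   source = if (is.character(msa)) msa[1] else "in-memory MSA")
}

#' Normalize conservation scores to z-scores
#'
#' Same contract as [normalize_profile()] (population standard
#' deviation), applied to the `score` column. The orientation is
#' untouched: low z still means conserved.
#'
#' @param cons a conservation profile tibble.
#' @return the profile with z-scored `score` and `normalized = TRUE`.
#' @export
normalize_conservation <- function(cons) {
  out <- cons
  out$score <- z_norm(cons$score, what = "conservation profile")
  attr(out, "normalized") <- TRUE
  out
}

#' Map conservation sites onto structure residues
#'
#' Site p is paired with the residue of the chosen subunit whose author
#' number is `p + offset` (blank insertion code). The mapping is by
#' residue numbering, not by alignment: it is transparent and adequate
#' for single-chain viral proteins whose deposited numbering follows the
#' sequence. Residues with insertion codes are left unmapped (Rate4Site
#' sites carry no insertion code). Amino-acid letters are compared where
#' both sides know them; if the disagreement fraction exceeds
#' `max_mismatch` the mapping fails (use `force = TRUE` to keep it, e.g.
#' for engineered point mutants).
#'
#' @param cons a conservation profile tibble.
#' @param model a C-alpha model.
#' @param subunit subunit id of the model to map onto.
#' @param offset integer added to site positions to obtain residue
#'   numbers (default 0).
#' @param max_mismatch maximal tolerated fraction of amino-acid
#'   disagreements among compared pairs (default 0.05).
#' @param force keep the mapping even above `max_mismatch`.
#' @return a `site_map`: list with `pairs`, `unmapped_structure`,
#'   `unmapped_sites` and `mismatches` tibbles.
#' @export
map_to_structure <- function(cons, model, subunit, offset = 0,
                             max_mismatch = 0.05, force = FALSE) {
  model <- as_calpha_model(model, source = attr(model, "source"))
  rows <- subunit_rows(model, subunit)
  res <- as_tibble(model[rows, ])
  icoded <- res[res$icode != "", ]
  res <- res[res$icode == "", ]
  target <- cons$pos + as.integer(offset)
  hit <- match(res$seq_num, target)
  paired <- !is.na(hit)
  pairs <- tibble(subunit = res$subunit[paired],
                  seq_num = res$seq_num[paired],
                  icode = res$icode[paired],
                  aa = res$aa[paired],
                  pos = cons$pos[hit[paired]],
                  site_aa = cons$aa[hit[paired]],
                  score = cons$score[hit[paired]])
  if (nrow(pairs) == 0) {
    abort(paste0("no overlap between conservation sites (offset ", offset,
                 ") and subunit '", subunit, "' residues"),
          class = "capsidprof_input_error")
  }
  compared <- !is.na(pairs$site_aa) & pairs$aa != "X"
  mism <- pairs[compared & pairs$aa != pairs$site_aa, ]
  frac <- if (any(compared)) nrow(mism) / sum(compared) else 0
  if (frac > max_mismatch && !force) {
    shown <- utils::head(sprintf("%s/%d %s vs site %d %s", mism$subunit,
                                 mism$seq_num, mism$aa, mism$pos,
                                 mism$site_aa), 10)
    abort(paste0(sprintf(
      "amino-acid mismatch fraction %.1f%% exceeds %.1f%% (offset wrong?):\n  ",
      100 * frac, 100 * max_mismatch),
      paste(shown, collapse = "\n  "),
      "\nuse force = TRUE to keep the mapping"),
      class = "capsidprof_mapping_error")
  }
  structure(list(
    pairs = pairs,
    unmapped_structure = bind_rows(
      icoded[, c("subunit", "seq_num", "icode", "aa")],
      res[!paired, c("subunit", "seq_num", "icode", "aa")]),
    unmapped_sites = as_tibble(cons)[!cons$pos %in% pairs$pos,
                                     c("pos", "aa", "score")],
    mismatches = mism,
    offset = as.integer(offset)),
    class = "site_map")
}

#' @export
print.site_map <- function(x, ...) {
  cat(sprintf(paste0("<site_map> %d pairs, %d unmapped residues, ",
                     "%d unmapped sites, %d mismatches (offset %d)\n"),
              nrow(x$pairs), nrow(x$unmapped_structure),
              nrow(x$unmapped_sites), nrow(x$mismatches), x$offset))
  invisible(x)
}
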