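#' C-alpha capsid models
#'
#' A C-alpha model is a tibble with one row per residue, holding the Calpha
#' coordinate and a stable residue key. It is the common currency of the
#' package: structure readers produce it, the assembly expander transforms
#' it, and both structural profiles consume it.
#'
#' Columns:
#' \describe{
#'   \item{subunit}{assembly-instance identifier, `"<chain>"` for the
#'     asymmetric unit or `"<chain>.<k>"` for the copy produced by the k-th
#'     symmetry operator (1-based).}
#'   \item{chain}{author chain identifier.}
#'   \item{seq_num}{author residue number (integer).}
#'   \item{icode}{insertion code, `""` when absent.}
#'   \item{aa}{one-letter amino-acid code, `"X"` for nonstandard residues
#'     without a parent mapping.}
#'   \item{x, y, z}{Calpha coordinates in Angstrom.}
#' }
#'
#' @param df a data frame with the columns above.
#' @param source character scalar describing provenance (file path,
#'   assembly id, or generator call).
#'
#' @return `as_calpha_model()` returns the validated tibble with class
#'   `"calpha_model"` and a `"source"` attribute.
#' @export
as_calpha_model <- function(df, source = NA_character_) {
  df <- as_tibble(df)
  needed <- c("subunit", "chain", "seq_num", "icode", "aa", "x", "y", "z")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("not a C-alpha model: missing column(s) ",
                 paste(missing_cols, collapse = ", ")),
          class = "capsidprof_input_error")
  }
  if (nrow(df) < 1) {
    abort("empty model: no C-alpha records", class = "capsidprof_input_error")
  }
  df$seq_num <- as.integer(df$seq_num)
  df$icode[is.na(df$icode)] <- ""
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("non-finite coordinates in model", class = "capsidprof_input_error")
  }
  key <- paste(df$subunit, df$seq_num, df$icode, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    abort(paste0("duplicate residue key within model: ",
                 gsub("\r", "/", dup)),
          class = "capsidprof_input_error")
  }
  bad_aa <- setdiff(unique(df$aa), c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X"))
  if (length(bad_aa) > 0) {
    abort(paste0("invalid amino-acid letter(s): ", paste(bad_aa, collapse = ", ")),
          class = "capsidprof_input_error")
  }
  structure(df,
            class = c("calpha_model", class(as_tibble(df))),
            source = source)
}

#' @rdname as_calpha_model
#' @param x object to test.
#' @export
is_calpha_model <- function(x) inherits(x, "calpha_model")

#' List the subunits of a model
#'
#' @param model a C-alpha model (see [as_calpha_model()]).
#' @return character vector of subunit ids in model order.
#' @export
model_subunits <- function(model) unique(model$subunit)

#' @export
print.calpha_model <- function(x, ...) {
  src <- attr(x, "source")
  cat(sprintf("<calpha_model> %d residues, %d subunit(s)%s\n",
              nrow(x), length(unique(x$subunit)),
              if (is.na(src)) "" else paste0(" | ", src)))
  NextMethod()
  invisible(x)
}

# Coordinate matrix (n x 3) of a model or a subset of rows.
coord_matrix <- function(model, rows = NULL) {
  if (is.null(rows)) {
    cbind(model$x, model$y, model$z)
  } else {
    cbind(model$x[rows], model$y[rows], model$z[rows])
  }
}

# Resolve a subunit selector ("all" or an id) to row indices.
subunit_rows <- function(model, subunit) {
  if (identical(subunit, "all")) return(seq_len(nrow(model)))
  rows <- which(model$subunit == subunit)
  if (length(rows) == 0) {
    abort(paste0("subunit not found in model: '", subunit, "' (available: ",
                 paste(utils::head(model_subunits(model), 8), collapse = ", "),
                 if (length(model_subunits(model)) > 8) ", ..." else "", ")"),
          class = "capsidprof_input_error")
  }
  rows
}

# Residue label for error messages.
residue_label <- function(model, i) {
  sprintf("%s/%d%s(%s)", model$subunit[i], model$seq_num[i],
          model$icode[i], model$aa[i])
}
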