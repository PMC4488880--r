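# Minimal reader for the two mmCIF categories that carry biological
# assembly operators: _pdbx_struct_oper_list (the rigid-body matrices)
# and _pdbx_struct_assembly_gen (which operators build which assembly).
# Coordinate parsing itself is bio3d's job; no installed package exposes
# these categories, so they are read here. Handles both the loop_ and the
# single-record key-value forms; multi-line (semicolon) values are not
# expected in these categories and are rejected.

cif_split_row <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  tok <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

# Returns a data frame with one column per item of the category, or NULL.
cif_category <- function(lines, category) {
  prefix <- paste0("_", category, ".")
  hit <- grep(prefix, lines, fixed = TRUE)
  if (length(hit) == 0) return(NULL)

  # loop_ form: tags on their own lines, then data rows.
  first <- hit[1]
  loop_starts <- grep("^\\s*loop_\\s*$", lines)
  loop_before <- loop_starts[loop_starts < first]
  tagline <- trimws(lines[first])
  if (startsWith(tagline, prefix) && length(cif_split_row(tagline)) == 1 &&
      length(loop_before) > 0 &&
      all(startsWith(trimws(lines[(utils::tail(loop_before, 1) + 1):first]),
                     prefix))) {
    # collect tags
    i <- first
    tags <- character(0)
    while (i <= length(lines) && startsWith(trimws(lines[i]), prefix)) {
      tags <- c(tags, sub(prefix, "", cif_split_row(trimws(lines[i]))[1],
                          fixed = TRUE))
      i <- i + 1
    }
    rows <- list()
    buf <- character(0)
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || startsWith(ln, "_") || startsWith(ln, "loop_") ||
          startsWith(ln, "#") || startsWith(ln, "data_")) break
      if (startsWith(ln, ";")) {
        abort(paste0("multi-line values unsupported in _", category),
              class = "capsidprof_format_error")
      }
      buf <- c(buf, cif_split_row(ln))
      while (length(buf) >= length(tags)) {
        rows[[length(rows) + 1]] <- buf[seq_along(tags)]
        buf <- buf[-seq_along(tags)]
      }
      i <- i + 1
    }
    if (length(rows) == 0) return(NULL)
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- tags
    return(df)
  }

  # key-value form: "_cat.tag value" lines, one record.
  kv <- lines[hit]
  tok <- lapply(trimws(kv), cif_split_row)
  ok <- vapply(tok, length, 1L) >= 2
  tok <- tok[ok]
  if (length(tok) == 0) return(NULL)
  tags <- vapply(tok, function(t) sub(prefix, "", t[1], fixed = TRUE), "")
  vals <- vapply(tok, function(t) t[2], "")
  df <- as.data.frame(as.list(vals), stringsAsFactors = FALSE,
                      col.names = tags)
  names(df) <- tags
  df
}

# Expand an oper_expression like "1", "1,2,5", "(1-60)" into operator ids.
parse_oper_expression <- function(expr) {
  if (grepl("\\)\\s*\\(", expr)) {
    abort(paste0("composed operator expressions ('", expr,
                 "') are not supported; supply an external operator file"),
          class = "capsidprof_input_error")
  }
  expr <- gsub("[()\\s]", "", expr)
  parts <- strsplit(expr, ",", fixed = TRUE)[[1]]
  unlist(lapply(parts, function(p) {
    if (grepl("^[0-9]+-[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      as.character(seq(ab[1], ab[2]))
    } else p
  }))
}

# Rigid transforms for one mmCIF assembly id. The operators are applied
# to the whole model: per-chain operator lists (asym_id_list) would need
# the label->author chain mapping, which Calpha-level capsid work does
# not require; capsid depositions use one expression for all chains.
mmcif_transforms <- function(path, assembly) {
  lines <- readLines(path, warn = FALSE)
  opers <- cif_category(lines, "pdbx_struct_oper_list")
  if (is.null(opers)) {
    abort("no _pdbx_struct_oper_list in mmCIF file; pass `transforms`",
          class = "capsidprof_input_error")
  }
  need <- c("id",
            paste0("matrix[", rep(1:3, each = 3), "][", rep(1:3, 3), "]"),
            paste0("vector[", 1:3, "]"))
  if (!all(need %in% names(opers))) {
    abort("incomplete _pdbx_struct_oper_list (missing matrix/vector items)",
          class = "capsidprof_format_error")
  }
  tfs <- lapply(seq_len(nrow(opers)), function(i) {
    R <- matrix(as.numeric(c(
      opers[i, "matrix[1][1]"], opers[i, "matrix[1][2]"], opers[i, "matrix[1][3]"],
      opers[i, "matrix[2][1]"], opers[i, "matrix[2][2]"], opers[i, "matrix[2][3]"],
      opers[i, "matrix[3][1]"], opers[i, "matrix[3][2]"], opers[i, "matrix[3][3]"]
    )), 3, 3, byrow = TRUE)
    list(rotation = R,
         translation = as.numeric(c(opers[i, "vector[1]"],
                                    opers[i, "vector[2]"],
                                    opers[i, "vector[3]"])))
  })
  names(tfs) <- opers$id

  gen <- cif_category(lines, "pdbx_struct_assembly_gen")
  if (is.null(gen)) return(unname(tfs))
  rows <- gen[gen$assembly_id == as.character(assembly), , drop = FALSE]
  if (nrow(rows) == 0) {
    abort(paste0("unknown assembly id '", assembly, "' (file has: ",
                 paste(unique(gen$assembly_id), collapse = ", "), ")"),
          class = "capsidprof_input_error")
  }
  ids <- unique(unlist(lapply(rows$oper_expression, parse_oper_expression)))
  missing_ids <- setdiff(ids, names(tfs))
  if (length(missing_ids) > 0) {
    abort(paste0("assembly references undefined operator(s): ",
                 paste(missing_ids, collapse = ", ")),
          class = "capsidprof_format_error")
  }
  unname(tfs[ids])
}
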