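# Three-letter -> one-letter residue codes. Standard 20 plus common
# modified residues with an unambiguous parent; everything else becomes X.
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S",
  TPO = "T", PTR = "Y", CSO = "C", MLY = "K"
)

AA_ONE_TO_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
  X = "UNK"
)

# Chain alphabet used when subunit ids must be squeezed into the 1-char
# PDB chain field (62 symbols; beyond that pdb_bfactor export refuses).
CHAIN_ALPHABET <- c(LETTERS, letters, as.character(0:9))

#' Read a structure into a C-alpha model
#'
#' Parses a PDB or mmCIF file, reduces every residue to its Calpha atom and
#' returns a [C-alpha model][as_calpha_model]. When `assembly` names a
#' biological assembly, the stored symmetry operators (REMARK 350 BIOMT for
#' PDB, `_pdbx_struct_oper_list` for mmCIF) are applied via
#' [expand_assembly()] so the returned model is the full capsid.
#'
#' Altloc policy: among alternate Calpha locations of one residue the
#' highest-occupancy record wins, ties broken by file order. Protein
#' residues without a Calpha are skipped with a message. Waters, ions and
#' other hetero compounds carry no Calpha carbon and are excluded.
#'
#' @param path path to a PDB or mmCIF file.
#' @param format `"auto"` (by file extension), `"pdb"` or `"mmcif"`.
#' @param assembly `"asu"` for the deposited coordinates, or an assembly
#'   identifier (e.g. `1`) to expand with the file's stored operators.
#' @param transforms optional external operators overriding the file's:
#'   a path accepted by [read_transforms()] or a list of transforms.
#' @return a `calpha_model` tibble.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' m0 <- make_shell_capsid(n_subunits = 2, residues_per_subunit = 20,
#'                         radii = 30, seed = 1)
#' write_colored_structure(m0, wcn_profile(m0), pdb, mode = "pdb_bfactor")
#' read_structure(pdb)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           assembly = "asu", transforms = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("structure file not found: ", path),
          class = "capsidprof_input_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) {
      abort(paste0("cannot parse ", format, " file '", path, "': ",
                   conditionMessage(e)),
            class = "capsidprof_format_error")
    })

  atoms <- as_tibble(pdb$atom)
  atoms$row0 <- seq_len(nrow(atoms))
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$o[is.na(atoms$o)] <- 1

  is_ca <- atoms$elety == "CA" &
    (is.na(atoms$elesy) | atoms$elesy %in% c("C", ""))
  # Hetero records only count when they are CA carbons of a known
  # modified residue (e.g. MSE); plain HETATM "CA" is a calcium ion.
  het <- atoms$type == "HETATM"
  is_ca <- is_ca & (!het | atoms$resid %in% names(AA_THREE_TO_ONE))
  ca <- atoms[is_ca, , drop = FALSE]
  if (nrow(ca) == 0) {
    abort(paste0("no C-alpha atoms in '", path, "'"),
          class = "capsidprof_input_error")
  }

  # Highest-occupancy altloc, ties by file order.
  ca <- ca[order(ca$chain, ca$resno, ca$insert, -ca$o, ca$row0), ]
  keep <- !duplicated(paste(ca$chain, ca$resno, ca$insert, sep = "\r"))
  ca <- ca[keep, , drop = FALSE]
  ca <- ca[order(ca$row0), , drop = FALSE]

  # Protein residues with atoms but no usable CA: skip with a message.
  prot <- atoms[atoms$type == "ATOM" | atoms$resid %in% names(AA_THREE_TO_ONE), ]
  all_res <- unique(paste(prot$chain, prot$resno, prot$insert, sep = "\r"))
  got_res <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
  miss <- setdiff(all_res, got_res)
  if (length(miss) > 0) {
    inform(paste0("skipped ", length(miss),
                  " residue(s) without a C-alpha atom in '", basename(path),
                  "' (e.g. ", gsub("\r", "/", miss[1]), ")"))
  }

  aa <- unname(AA_THREE_TO_ONE[ca$resid])
  aa[is.na(aa)] <- "X"
  model <- as_calpha_model(
    tibble(subunit = as.character(ca$chain),
           chain = as.character(ca$chain),
           seq_num = as.integer(ca$resno),
           icode = as.character(ca$insert),
           aa = aa,
           x = ca$x, y = ca$y, z = ca$z),
    source = paste0(path, " [", format, ", assembly=", assembly, "]"))
  # Chain blocks ordered by (seq_num, icode) within each chain.
  model <- as_calpha_model(
    arrange(model, match(.data$subunit, unique(model$subunit)),
            .data$seq_num, .data$icode),
    source = attr(model, "source"))

  if (identical(assembly, "asu") && is.null(transforms)) return(model)

  if (!is.null(transforms)) {
    tfs <- if (is.character(transforms)) read_transforms(transforms) else transforms
  } else if (format == "pdb") {
    tfs <- biomt_transforms(pdb, assembly)
  } else {
    tfs <- mmcif_transforms(path, assembly)
  }
  expand_assembly(model, tfs)
}

# Transforms of one REMARK 350 biomolecule, as parsed by bio3d.
biomt_transforms <- function(pdb, assembly) {
  bm <- pdb$remark$biomat
  if (is.null(bm)) {
    abort("no REMARK 350 assembly operators in file; pass `transforms`",
          class = "capsidprof_input_error")
  }
  idx <- suppressWarnings(as.integer(assembly))
  if (is.na(idx) || idx < 1 || idx > bm$num) {
    abort(paste0("unknown assembly id '", assembly, "' (file has ",
                 bm$num, ")"),
          class = "capsidprof_input_error")
  }
  lapply(bm$mat[[idx]], function(m) {
    list(rotation = m[, 1:3, drop = FALSE], translation = m[, 4])
  })
}

#' Read rigid-body operators from a plain-text file
#'
#' One operator per non-comment row: 12 whitespace-separated numbers, the
#' rotation matrix in row-major order followed by the translation in
#' Angstrom (`r11 r12 r13 r21 r22 r23 r31 r32 r33 t1 t2 t3`).
#'
#' @param path path to the operator file.
#' @return list of transforms, each `list(rotation = <3x3>, translation = <3>)`.
#' @export
read_transforms <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("operator file not found: ", path),
          class = "capsidprof_input_error")
  }
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (length(ln) == 0) {
    abort("operator file has no data rows", class = "capsidprof_input_error")
  }
  lapply(seq_along(ln), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(ln[[i]], "\\s+")[[1]]))
    if (length(v) != 12 || anyNA(v)) {
      abort(paste0("operator file line ", i, ": expected 12 numbers"),
            class = "capsidprof_input_error")
    }
    list(rotation = matrix(v[1:9], 3, 3, byrow = TRUE), translation = v[10:12])
  })
}

check_rigid <- function(tf, k) {
  R <- tf$rotation
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
    abort(paste0("transform ", k, ": rotation is not a proper orthonormal ",
                 "matrix (R'R = I, det = +1 required)"),
          class = "capsidprof_input_error")
  }
  invisible(tf)
}

#' Expand a model with rigid-body symmetry operators
#'
#' Applies each operator `x' = R x + t` to every residue, producing one
#' copy of every input subunit per operator. Output order is
#' transform-major (all subunits under operator 1, then operator 2, ...).
#' With a single operator the subunit ids are kept; with several, copy k
#' of chain C is named `"C.k"`.
#'
#' @param model a C-alpha model.
#' @param transforms list of `list(rotation = <3x3>, translation = <3>)`;
#'   rotations must be proper orthonormal matrices.
#' @return the expanded `calpha_model`.
#' @export
expand_assembly <- function(model, transforms) {
  model <- as_calpha_model(model, source = attr(model, "source"))
  transforms <- unname(transforms)
  if (length(transforms) == 0) {
    abort("no transforms supplied", class = "capsidprof_input_error")
  }
  purrr::iwalk(transforms, function(tf, k) check_rigid(tf, k))
  X <- coord_matrix(model)
  copies <- purrr::imap(transforms, function(tf, k) {
    Xi <- X %*% t(tf$rotation)
    Xi <- sweep(Xi, 2, tf$translation, "+")
    out <- as_tibble(model)
    out$x <- Xi[, 1]; out$y <- Xi[, 2]; out$z <- Xi[, 3]
    if (length(transforms) > 1) {
      out$subunit <- paste0(out$subunit, ".", k)
    }
    out
  })
  as_calpha_model(bind_rows(copies),
                  source = paste0(attr(model, "source"), " x",
                                  length(transforms), " operators"))
}

#' Export a score-colored structure
#'
#' Writes a structure whose per-residue values can drive coloring in a
#' molecular viewer, in the continuous low-to-high (blue-to-red) scheme
#' used for radius- or conservation-colored capsid surfaces.
#'
#' `pdb_bfactor` mode writes a Calpha-only PDB with the B-factor column
#' carrying the profile value (fixed-width `%6.2f`; values outside
#' -99.99..999.99 are clamped with a message). `attribute_table` mode
#' writes a TSV (subunit, chain, seq_num, icode, aa, value) for
#' viewer-side coloring. Model residues without a profile value get 0 and
#' are reported.
#'
#' @param model a C-alpha model.
#' @param profile a profile tibble keyed by (subunit, seq_num, icode) with
#'   a `value` column, e.g. from [wcn_profile()] or [normalize_profile()].
#' @param path output file path.
#' @param mode `"pdb_bfactor"` or `"attribute_table"`.
#' @return `path`, invisibly.
#' @export
write_colored_structure <- function(model, profile, path,
                                    mode = c("pdb_bfactor", "attribute_table")) {
  mode <- match.arg(mode)
  model <- as_calpha_model(model, source = attr(model, "source"))
  if (!"value" %in% names(profile)) {
    abort("profile must have a `value` column", class = "capsidprof_input_error")
  }
  prof <- as_tibble(profile)[, c("subunit", "seq_num", "icode", "value")]
  key_m <- paste(model$subunit, model$seq_num, model$icode, sep = "\r")
  key_p <- paste(prof$subunit, prof$seq_num, prof$icode, sep = "\r")
  if (any(!key_p %in% key_m)) {
    abort(paste0(sum(!key_p %in% key_m),
                 " profile residue(s) absent from the model"),
          class = "capsidprof_input_error")
  }
  val <- prof$value[match(key_m, key_p)]
  n_missing <- sum(is.na(val))
  if (n_missing == length(val)) {
    abort("profile and model share no residues", class = "capsidprof_input_error")
  }
  if (n_missing > 0) {
    inform(paste0(n_missing, " model residue(s) have no profile value; ",
                  "written as 0.00"))
    val[is.na(val)] <- 0
  }

  if (mode == "attribute_table") {
    out <- tibble(subunit = model$subunit, chain = model$chain,
                  seq_num = model$seq_num, icode = model$icode,
                  aa = model$aa, value = val)
    readr::write_tsv(out, path)
    return(invisible(path))
  }

  clamped <- val < -99.99 | val > 999.99
  if (any(clamped)) {
    inform(paste0(sum(clamped), " value(s) clamped to the B-factor field ",
                  "range [-99.99, 999.99]"))
    val <- pmin(pmax(val, -99.99), 999.99)
  }
  sub_ids <- unique(model$subunit)
  if (length(sub_ids) > length(CHAIN_ALPHABET)) {
    abort(paste0("pdb_bfactor export supports at most ",
                 length(CHAIN_ALPHABET), " subunits (got ",
                 length(sub_ids), "); use attribute_table mode"),
          class = "capsidprof_input_error")
  }
  chain1 <- if (all(nchar(sub_ids) == 1)) sub_ids
            else CHAIN_ALPHABET[seq_along(sub_ids)]
  names(chain1) <- sub_ids
  resid3 <- unname(AA_ONE_TO_THREE[model$aa])
  resid3[is.na(resid3)] <- "UNK"
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coord_matrix(model))),
                   resno = model$seq_num,
                   resid = resid3,
                   eleno = seq_len(nrow(model)),
                   elety = rep("CA", nrow(model)),
                   chain = unname(chain1[model$subunit]),
                   insert = ifelse(model$icode == "", NA, model$icode),
                   o = rep(1, nrow(model)),
                   b = val,
                   end = TRUE)
  invisible(path)
}
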