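# Fixtures are built in code at test time: tiny C-alpha models, minimal
# PDB files written field-by-field, and independently written oracles
# for the quantities the package computes.

`%||%` <- function(a, b) if (is.null(a)) b else a

coord_unname <- function(model) unname(cbind(model$x, model$y, model$z))

toy_model <- function(X, subunit = "A", seq_num = seq_len(nrow(X)),
                      aa = NULL) {
  X <- as.matrix(X)
  aa <- aa %||% rep(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                    length.out = nrow(X))
  as_calpha_model(tibble::tibble(
    subunit = rep(subunit, length.out = nrow(X)),
    chain = substr(rep(subunit, length.out = nrow(X)), 1, 1),
    seq_num = seq_num, icode = "", aa = aa,
    x = X[, 1], y = X[, 2], z = X[, 3]))
}

pdb_atom_line <- function(serial, resid, chain, resno, x, y, z,
                          occ = 1, b = 0, alt = " ", icode = " ",
                          elety = " CA ") {
  paste0("ATOM  ", sprintf("%5d", serial), " ", elety, alt,
         sprintf("%3s", resid), " ", chain, sprintf("%4d", resno), icode,
         "   ", sprintf("%8.3f%8.3f%8.3f%6.2f%6.2f", x, y, z, occ, b),
         "           C")
}

# REMARK 350 block for rotations about z by `angles` (degrees) with the
# given translations (list of 3-vectors).
biomt_block <- function(angles, translations = NULL, chains = "A") {
  translations <- translations %||% rep(list(c(0, 0, 0)), length(angles))
  rows <- unlist(lapply(seq_along(angles), function(k) {
    th <- angles[k] * pi / 180
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    t <- translations[[k]]
    sprintf("REMARK 350   BIOMT%d %3d %9.6f %9.6f %9.6f     %9.5f",
            1:3, k, R[, 1], R[, 2], R[, 3], t)
  }))
  c("REMARK 350 BIOMOLECULE: 1",
    paste0("REMARK 350 APPLY THE FOLLOWING TO CHAINS: ",
           paste(chains, collapse = ", ")),
    rows)
}

write_mini_pdb <- function(path, atom_lines, header = character(0)) {
  writeLines(c(header, atom_lines, "TER", "END"), path)
  path
}

# A 3-residue single-chain PDB (ALA1, LEU2, GLY3 with N+CA each).
mini_pdb_lines <- function() {
  c(pdb_atom_line(1, "ALA", "A", 1, 0, 0, 0, elety = " N  "),
    pdb_atom_line(2, "ALA", "A", 1, 1, 0, 0),
    pdb_atom_line(3, "LEU", "A", 2, 2, 0.5, 0, elety = " N  "),
    pdb_atom_line(4, "LEU", "A", 2, 3, 1, 0),
    pdb_atom_line(5, "GLY", "A", 3, 4, 2, 1))
}

# --- independent oracles -------------------------------------------------

# Brute-force double loop over Eq-style inverse-square sums; written
# independently of the package's blocked Gram-matrix implementation.
oracle_wcn <- function(X) {
  N <- nrow(X)
  n <- numeric(N)
  for (i in seq_len(N)) {
    d2 <- (X[, 1] - X[i, 1])^2 + (X[, 2] - X[i, 2])^2 + (X[, 3] - X[i, 3])^2
    n[i] <- sum(1 / d2[-i])
  }
  1 / n
}

# Textbook product-moment formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Random proper rotation + translation.
random_rigid <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(rotation = R, translation = runif(3, -50, 50))
}

apply_rigid <- function(model, tf) {
  expand_assembly(model, list(tf))
}

grades_lines <- function(pos, aa, score) {
  c("#Rates were calculated using the expectation of the posterior rate distribution",
    "#POS SEQ SCORE",
    sprintf("%4d %s %9.5f", pos, aa, score))
}
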