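#' Read the C-alpha trace of one chain from a PDB file
#'
#' Extracts one C-alpha coordinate per residue of a single chain and model,
#' in file order. Residue identity is the pair (residue number, insertion
#' code); ordering always follows the order of ATOM records in the file,
#' never a numeric sort, because deposited residue numbering need not be
#' monotone. Residues of the chain that lack a C-alpha atom are omitted with
#' a warning. Alternate locations are resolved to the highest-occupancy
#' conformer, ties broken by altloc identifier ascending.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier (single character).
#' @param model Model number, 1-based. Defaults to the first model, which is
#'   the only one present in X-ray entries.
#'
#' @return A tibble of class `calpha_trace` with one row per residue:
#'   `chain`, `resno` (integer), `ins` (insertion code, `""` when absent),
#'   `resname` (3-letter residue name) and coordinates `x`, `y`, `z` in
#'   Angstrom.
#'
#' @examples
#' sheet <- generate_flat_sheet(4)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(sheet$trace, sheet$annotation, f)
#' trace <- read_calpha_trace(f, chain = "A")
#' trace
#' @export
read_calpha_trace <- function(path, chain, model = 1) {
  if (!file.exists(path)) {
    bj_abort(paste0("PDB file not found: ", path), "missing_file")
  }
  pdb <- tryCatch(
    suppressWarnings(
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    ),
    error = function(e) {
      bj_abort(paste0("failed to parse PDB file ", path, ": ",
                      conditionMessage(e)), "parse")
    }
  )
  atoms <- as_tibble(pdb$atom)
  atoms <- filter(atoms, .data$type == "ATOM")
  if (!chain %in% atoms$chain) {
    bj_abort(paste0("chain '", chain, "' not present in ", path,
                    " (chains: ", paste(sort(unique(atoms$chain)), collapse = ", "), ")"),
             "unknown_chain")
  }

  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model < 1 || model > n_models) {
    bj_abort(paste0("model ", model, " requested but file has ", n_models,
                    " model(s)"), "unknown_model")
  }
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  coords <- matrix(xyz, ncol = 3, byrow = TRUE)

  idx <- which(pdb$atom$type == "ATOM" & pdb$atom$chain == chain)
  at <- as_tibble(pdb$atom[idx, , drop = FALSE])
  at$x <- coords[idx, 1]
  at$y <- coords[idx, 2]
  at$z <- coords[idx, 3]
  at$ins <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$o <- ifelse(is.na(at$o), 1, at$o)

  # residues in file order
  rid <- paste(at$resno, at$ins)
  res_order <- unique(rid)

  ca <- at[at$elety == "CA", , drop = FALSE]
  missing_ca <- setdiff(res_order, paste(ca$resno, ca$ins))
  if (length(missing_ca) > 0) {
    bj_warn(paste0(length(missing_ca), " residue(s) on chain ", chain,
                   " lack a C-alpha atom and were omitted: ",
                   paste(head(missing_ca, 5), collapse = ", "),
                   if (length(missing_ca) > 5) ", ..." else ""),
            "missing_calpha")
  }
  if (nrow(ca) == 0) {
    bj_abort(paste0("no C-alpha atoms on chain ", chain, " in ", path),
             "no_calpha")
  }

  # altloc resolution: highest occupancy, ties by altloc id ascending
  ca <- ca[order(match(paste(ca$resno, ca$ins), res_order), -ca$o, ca$alt), ]
  ca <- ca[!duplicated(paste(ca$resno, ca$ins)), ]

  new_calpha_trace(
    chain = chain, resno = as.integer(ca$resno), ins = ca$ins,
    resname = ca$resid, x = ca$x, y = ca$y, z = ca$z
  )
}

new_calpha_trace <- function(chain, resno, ins, resname, x, y, z) {
  out <- tibble(
    chain = chain, resno = as.integer(resno), ins = as.character(ins),
    resname = as.character(resname), x = as.numeric(x), y = as.numeric(y),
    z = as.numeric(z)
  )
  if (anyDuplicated(paste(out$resno, out$ins))) {
    bj_abort("duplicate residue identifiers in C-alpha trace", "parse")
  }
  class(out) <- c("calpha_trace", class(out))
  out
}

#' @export
print.calpha_trace <- function(x, ...) {
  cat("<calpha_trace> chain ", x$chain[1], ", ", nrow(x), " residues\n", sep = "")
  NextMethod()
}
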