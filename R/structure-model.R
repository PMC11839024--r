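#' Construct a structure model
#'
#' A `structure_model` holds Calpha coordinates for one or more chains, a
#' per-residue confidence value (pLDDT scale, `NA` for experimental
#' structures), and the chain-to-accession mapping that reconciles
#' structure-internal residue numbering with 1-based full-length sequence
#' positions (structure residue 1 = full-length position `offset + 1`).
#'
#' @param atoms Tibble with columns `chain`, `resno`, `x`, `y`, `z`,
#'   `plddt`.
#' @param chain_map Tibble with columns `chain`, `accession`, `offset`.
#' @param source One of `"PDB"`, `"pairwise-prediction"`,
#'   `"link-assisted-prediction"`, `"synthetic"`.
#' @param model_id Identifier string.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, chain_map,
                            source = c("synthetic", "PDB", "pairwise-prediction",
                                       "link-assisted-prediction"),
                            model_id = "model") {
  source <- match.arg(source)
  stopifnot(all(c("chain", "resno", "x", "y", "z", "plddt") %in% names(atoms)),
            all(c("chain", "accession", "offset") %in% names(chain_map)))
  coords <- as.matrix(atoms[c("x", "y", "z")])
  if (any(!is.finite(coords[!is.na(coords)]))) abort("coordinates must be finite")
  missing_map <- setdiff(unique(atoms$chain), chain_map$chain)
  if (length(missing_map)) {
    abort(sprintf("chains without accession mapping: %s",
                  paste(missing_map, collapse = ", ")))
  }
  structure(list(atoms = as_tibble(atoms), chain_map = as_tibble(chain_map),
                 source = source, model_id = model_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model '%s' (%s): %d chains, %d residues>\n",
              x$model_id, x$source, nrow(x$chain_map), nrow(x$atoms)))
  print(x$chain_map)
  invisible(x)
}

#' Residue table of a model in full-length coordinates
#'
#' Joins the atom table to the chain map, adding `accession` and `position`
#' (= `resno + offset`, 1-based full-length).
#'
#' @param model A `structure_model`.
#' @return Tibble: `chain`, `resno`, `accession`, `position`, `x`, `y`, `z`,
#'   `plddt`.
#' @export
model_positions <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  out <- dplyr::inner_join(model$atoms, model$chain_map, by = "chain")
  out$position <- out$resno + out$offset
  out[c("chain", "resno", "accession", "position", "x", "y", "z", "plddt")]
}

#' Write a structure model as a PDB file
#'
#' Calpha-only records; the per-residue confidence is stored in the B-factor
#' column, following the convention of predicted-model files.
#'
#' @param model A `structure_model`.
#' @param file Output path (`.pdb`).
#' @return `file`, invisibly.
#' @export
write_structure <- function(model, file) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(
    file = file,
    xyz = as.vector(t(as.matrix(a[c("x", "y", "z")]))),
    resno = a$resno,
    chain = a$chain,
    resid = rep("ALA", nrow(a)),
    elety = rep("CA", nrow(a)),
    b = ifelse(is.na(a$plddt), 0, a$plddt),
    o = rep(1, nrow(a))
  )
  invisible(file)
}

#' Load a structural model from a PDB or mmCIF file
#'
#' Reads Calpha atoms (author numbering), takes the B-factor column as
#' pLDDT for predicted models, and attaches the supplied chain-to-accession
#' mapping. Chains named in `chain_map` but absent from the file are an
#' error; file chains absent from `chain_map` are dropped with a warning.
#'
#' @param file Path to a `.pdb` or `.cif` file.
#' @param chain_map Tibble `chain`, `accession`, `offset`.
#' @param source Model provenance; `"PDB"` leaves `plddt` as `NA` so the
#'   confidence gate is skipped for experimental structures.
#' @param model_id Identifier (defaults to the file name).
#' @return A `structure_model`.
#' @export
load_structure <- function(file, chain_map,
                           source = c("pairwise-prediction", "PDB",
                                      "link-assisted-prediction", "synthetic"),
                           model_id = NULL) {
  source <- match.arg(source)
  pdb <- if (grepl("\\.cif$", file, ignore.case = TRUE)) {
    bio3d::read.cif(file, verbose = FALSE)
  } else {
    bio3d::read.pdb(file, verbose = FALSE)
  }
  at <- pdb$atom[pdb$atom$elety == "CA", ]
  if (nrow(at) == 0) abort("no Calpha atoms found in file")
  missing <- setdiff(chain_map$chain, unique(at$chain))
  if (length(missing)) {
    abort(sprintf("file lacks mapped chain(s): %s", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(unique(at$chain), chain_map$chain)
  if (length(extra)) {
    warn(sprintf("dropping unmapped chain(s): %s", paste(extra, collapse = ", ")))
    at <- at[at$chain %in% chain_map$chain, ]
  }
  atoms <- tibble(
    chain = at$chain, resno = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z,
    plddt = if (source == "PDB") NA_real_ else at$b
  )
  structure_model(atoms, chain_map, source = source,
                  model_id = model_id %||% basename(file))
}
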