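# Internal Open Babel backend.
#
# All SMILES interpretation (parsing, aromaticity perception, Gasteiger
# charges, 3D building) is delegated to the `obabel` executable; nothing
# chemical is re-implemented here.  A fresh obabel process starts from a
# fixed internal RNG state, so every conversion is bitwise reproducible.

.ob_cache <- new.env(parent = emptyenv())

ob_available <- function() nzchar(Sys.which("obabel"))

#' @noRd
ob_run <- function(smiles, name, format = "mol2", addh = FALSE,
                   gasteiger = FALSE, gen3d = FALSE) {
  key <- paste(format, addh, gasteiger, gen3d, smiles, sep = "\r")
  hit <- .ob_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (!ob_available()) {
    stop("the 'obabel' executable was not found on PATH", call. = FALSE)
  }
  args <- c(paste0("-:", shQuote(paste(smiles, name))), paste0("-o", format))
  if (addh) args <- c(args, "-h")
  if (gen3d) args <- c(args, "--gen3d")
  if (gasteiger) args <- c(args, "--partialcharge", "gasteiger")
  out <- tempfile(fileext = paste0(".", format))
  err <- tempfile(fileext = ".err")
  on.exit(unlink(c(out, err)), add = TRUE)
  status <- suppressWarnings(
    system2("obabel", args, stdout = out, stderr = err)
  )
  errtxt <- paste(readLines(err, warn = FALSE), collapse = "\n")
  ok <- grepl("1 molecule converted", errtxt, fixed = TRUE)
  if (status != 0L || !ok || grepl("Error", errtxt)) {
    stop(sprintf("Open Babel could not convert SMILES for record '%s': %s",
                 name, sub(".*(Warning|Error)", "\\1", errtxt)),
         call. = FALSE)
  }
  res <- readLines(out, warn = FALSE)
  .ob_cache[[key]] <- res
  res
}

# Light syntactic pre-check: Open Babel silently repairs some malformed
# strings (e.g. an unclosed branch "C("), which must instead fail loudly.
#' @noRd
smiles_precheck <- function(smiles, id) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  if (length(chars) == 0L || !nzchar(trimws(smiles))) {
    stop(sprintf("record '%s': empty SMILES", id), call. = FALSE)
  }
  if (grepl("[[:space:]]", smiles)) {
    stop(sprintf("record '%s': SMILES contains whitespace", id), call. = FALSE)
  }
  paren <- cumsum((chars == "(") - (chars == ")"))
  if (any(paren < 0) || paren[length(paren)] != 0) {
    stop(sprintf("record '%s': unbalanced parentheses in SMILES '%s'",
                 id, smiles), call. = FALSE)
  }
  brack <- cumsum((chars == "[") - (chars == "]"))
  if (any(brack < 0 | brack > 1) || brack[length(brack)] != 0) {
    stop(sprintf("record '%s': unbalanced brackets in SMILES '%s'",
                 id, smiles), call. = FALSE)
  }
  invisible(TRUE)
}

#' @noRd
ob_read_mol2 <- function(lines) {
  f <- tempfile(fileext = ".mol2")
  on.exit(unlink(f), add = TRUE)
  writeLines(lines, f)
  bio3d::read.mol2(f)
}

# 3D conformers come from RDKit's seed-controlled distance-geometry
# embedding (ETKDG) with force-field relaxation, invoked through the
# python interpreter: Open Babel's own 3D builder runs a time-seeded rotor
# search for flexible molecules and is therefore not reproducible across
# processes.  Several embeddings are generated per molecule and the lowest
# force-field energy one kept; everything is driven by the caller's seed.

.rdkit_script <- '
import sys, json, csv
from rdkit import Chem
from rdkit.Chem import AllChem

inp, out, seed, nconf = sys.argv[1], sys.argv[2], int(sys.argv[3]), int(sys.argv[4])
res = {}
with open(inp) as fh:
    for row in csv.DictReader(fh):
        mid, smi = row["id"], row["smiles"]
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            res[mid] = {"error": "unparseable SMILES"}
            continue
        mol = Chem.AddHs(mol)
        params = AllChem.ETKDGv3()
        params.randomSeed = seed
        cids = AllChem.EmbedMultipleConfs(mol, numConfs=nconf, params=params)
        if len(cids) == 0:
            res[mid] = {"error": "embedding failed"}
            continue
        if AllChem.MMFFHasAllMoleculeParams(mol):
            opt = AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=500)
        else:
            opt = AllChem.UFFOptimizeMoleculeConfs(mol, maxIters=500)
        energies = [e for (_, e) in opt]
        best = list(cids)[min(range(len(energies)), key=energies.__getitem__)]
        conf = mol.GetConformer(best)
        elements, coords = [], []
        for atom in mol.GetAtoms():
            if atom.GetAtomicNum() > 1:
                p = conf.GetAtomPosition(atom.GetIdx())
                elements.append(atom.GetSymbol())
                coords.append([p.x, p.y, p.z])
        res[mid] = {"elements": elements, "coords": coords}
json.dump(res, open(out, "w"))
'

# Batch-embed 3D conformers for named SMILES; returns a named list of
# N x 3 heavy-atom coordinate matrices (plus element vectors for
# alignment checks).  Results are cached per (smiles, seed, n_confs).
#' @noRd
rdkit_embed_batch <- function(smiles, ids, seed = 0L, n_confs = 10L) {
  keys <- paste("rdkit3d", seed, n_confs, smiles, sep = "\r")
  need <- which(vapply(keys, function(k) is.null(.ob_cache[[k]]), logical(1)))
  if (length(need)) {
    if (!nzchar(Sys.which("python"))) {
      stop("the 'python' interpreter (with rdkit) was not found on PATH",
           call. = FALSE)
    }
    inp <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".json")
    script <- tempfile(fileext = ".py")
    on.exit(unlink(c(inp, out, script)), add = TRUE)
    utils::write.csv(data.frame(id = ids[need], smiles = smiles[need],
                                stringsAsFactors = FALSE),
                     inp, row.names = FALSE, quote = TRUE)
    writeLines(.rdkit_script, script)
    status <- suppressWarnings(system2("python",
                                       c(script, inp, out, seed, n_confs),
                                       stdout = FALSE, stderr = FALSE))
    if (status != 0L || !file.exists(out)) {
      stop("conformer embedding subprocess failed", call. = FALSE)
    }
    res <- jsonlite::read_json(out, simplifyVector = TRUE)
    for (k in need) {
      r <- res[[ids[k]]]
      if (is.null(r) || !is.null(r$error)) {
        stop(sprintf("record '%s': conformer embedding failed (%s)",
                     ids[k], if (is.null(r)) "no result" else r$error),
             call. = FALSE)
      }
      .ob_cache[[keys[k]]] <- list(elements = as.character(r$elements),
                                   coords = matrix(as.numeric(r$coords),
                                                   ncol = 3L))
    }
  }
  out <- lapply(keys, function(k) .ob_cache[[k]])
  names(out) <- ids
  out
}

# Formal charges come from the SDF "M  CHG" block (MOL2 carries none).
# Open Babel preserves input atom order, so rows align with the MOL2 atoms.
#' @noRd
ob_formal_charges <- function(smiles, name, n_heavy) {
  sdf <- ob_run(smiles, name, format = "sdf")
  fc <- integer(n_heavy)
  for (ln in grep("^M  CHG", sdf, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)),
                                "[[:space:]]+")[[1]])
    k <- toks[1]
    for (t in seq_len(k)) {
      idx <- toks[2 * t]
      if (idx <= n_heavy) fc[idx] <- toks[2 * t + 1]
    }
  }
  fc
}
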