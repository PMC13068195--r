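# Molecule container and library import.
#
# Heavy atoms only are stored; hydrogens are implicit, with the attached-H
# count kept per heavy atom (donor capacity is attributed to the heavy atom).
# SMILES and SDF import go through OpenBabel (obabel) for 3D embedding and
# SYBYL atom typing, and through ChemmineR for SDF coordinate fidelity.

#' Construct a molecule
#'
#' Low-level constructor used by the parsers and the synthetic generators.
#'
#' @param id Compound identifier.
#' @param elements Character vector of heavy-atom element symbols.
#' @param xyz Numeric n x 3 coordinate matrix (A).
#' @param bonds Data frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3; 1.5 for aromatic bonds).
#' @param charges Formal charge per atom (default 0).
#' @param aromatic Logical per atom (default FALSE).
#' @param nH Attached hydrogen count per heavy atom (default 0).
#' @param pcharges Partial charges used by the Coulomb term (defaults to
#'   `charges`).
#' @param classes Optional precomputed FragMap class per atom (see
#'   [classify_atoms()]); `NA` entries are classified on demand.
#' @param smiles Optional canonical SMILES of the record.
#' @return Object of class `molecule`.
#' @export
new_molecule <- function(id, elements, xyz, bonds,
                         charges = numeric(length(elements)),
                         aromatic = logical(length(elements)),
                         nH = integer(length(elements)),
                         pcharges = NULL, classes = NULL, smiles = NULL) {
  xyz <- rbind3(xyz)
  n <- length(elements)
  stopifnot(nrow(xyz) == n)
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (nrow(bonds) > 0 &&
      (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)))
    stop("bond indices out of range")
  structure(list(id = id, elements = elements, xyz = xyz, bonds = bonds,
                 charges = as.numeric(charges), aromatic = as.logical(aromatic),
                 nH = as.integer(nH),
                 pcharges = if (is.null(pcharges)) as.numeric(charges) else as.numeric(pcharges),
                 classes = classes, smiles = smiles),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("molecule '%s': %d heavy atoms, %d bonds%s\n", x$id,
              length(x$elements), nrow(x$bonds),
              if (!is.null(x$smiles)) paste0(", SMILES ", x$smiles) else ""))
  invisible(x)
}

n_atoms <- function(mol) length(mol$elements)

# ---- graph helpers -------------------------------------------------------

# adjacency list over heavy atoms
adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# matrix of pairwise bond-count distances (BFS from every atom)
bond_distances <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency(mol)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.infinite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# bonds that lie on a cycle (non-bridges), by removal + reachability
ring_bond_flags <- function(mol) {
  nb <- nrow(mol$bonds)
  flags <- logical(nb)
  if (nb == 0) return(flags)
  adj <- adjacency(mol)
  for (b in seq_len(nb)) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    # BFS from i avoiding the b-th bond; ring bond iff j still reachable
    seen <- logical(n_atoms(mol)); seen[i] <- TRUE
    frontier <- i
    while (length(frontier) && !seen[j]) {
      nxt <- integer(0)
      for (u in frontier) {
        vs <- adj[[u]]
        if (u == i) vs <- vs[!(vs == j & u == i)]  # drop the direct edge once
        vs <- setdiff(vs, which(seen))
        # ensure the direct i-j edge itself is skipped
        if (u == i) vs <- vs[!(vs == j)]
        nxt <- c(nxt, vs)
      }
      nxt <- unique(nxt)
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    flags[b] <- seen[j]
  }
  flags
}

# smallest rings (SSSR approximation): for each ring bond, the shortest cycle
# through it; deduplicated
find_rings <- function(mol, max_size = 8) {
  rb <- which(ring_bond_flags(mol))
  if (!length(rb)) return(list())
  adj <- adjacency(mol)
  rings <- list()
  for (b in rb) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    # BFS shortest path i -> j avoiding the direct edge
    prev <- rep(NA_integer_, n_atoms(mol))
    prev[i] <- 0L
    frontier <- i
    while (length(frontier) && is.na(prev[j])) {
      nxt <- integer(0)
      for (u in frontier) {
        vs <- adj[[u]]
        if (u == i) vs <- vs[vs != j]
        vs <- vs[is.na(prev[vs])]
        prev[vs] <- u
        nxt <- c(nxt, vs)
      }
      frontier <- unique(nxt)
    }
    if (is.na(prev[j])) next
    path <- j
    while (path[1] != i) path <- c(prev[path[1]], path)
    if (length(path) <= max_size) {
      key <- paste(sort(path), collapse = ",")
      rings[[key]] <- path
    }
  }
  unname(rings)
}

#' Rotatable torsions of a molecule
#'
#' A bond is rotatable when it is a single, acyclic bond between two
#' non-terminal heavy atoms. Each rotatable bond yields one torsion
#' quadruple (a, b, c, d) with a and d the lowest-index neighbors.
#'
#' @param mol A [new_molecule()].
#' @return Integer matrix with columns a, b, c, d (0 rows when rigid).
#' @export
rotatable_torsions <- function(mol) {
  out <- matrix(integer(0), ncol = 4,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  if (nrow(mol$bonds) == 0) return(out)
  adj <- adjacency(mol)
  deg <- lengths(adj)
  ring <- ring_bond_flags(mol)
  for (b in seq_len(nrow(mol$bonds))) {
    if (mol$bonds$order[b] != 1 || ring[b]) next
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    if (deg[i] < 2 || deg[j] < 2) next
    a <- min(setdiff(adj[[i]], j))
    d <- min(setdiff(adj[[j]], i))
    out <- rbind(out, c(a, i, j, d))
  }
  out
}

# atoms on the j-side of bond i-j (the set moved by a torsion about i-j)
distal_atoms <- function(mol, i, j) {
  adj <- adjacency(mol)
  seen <- logical(n_atoms(mol))
  seen[i] <- TRUE; seen[j] <- TRUE
  frontier <- j
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), which(seen))
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen[i] <- FALSE
  which(seen)
}

# ---- OpenBabel / mol2 import --------------------------------------------

obabel_available <- function() nzchar(Sys.which("obabel"))

run_obabel <- function(args) {
  out <- suppressWarnings(system2("obabel", args, stdout = TRUE, stderr = TRUE))
  out
}

sybyl_element <- function(ty) toupper(sub("\\..*$", "", ty))

# formal charges from the M  CHG lines of an SDF file, keyed by record title
sdf_formal_charges <- function(path) {
  txt <- readLines(path)
  recs <- split(txt, cumsum(c(1, utils::head(txt, -1) == "$$$$")))
  charges <- list(); titles <- character(0)
  for (r in recs) {
    if (length(r) < 4) next
    chg <- integer(0)
    for (l in grep("^M  CHG", r, value = TRUE)) {
      nums <- as.integer(strsplit(trimws(sub("^M  CHG\\s*\\d+", "", l)), "\\s+")[[1]])
      if (length(nums) >= 2) {
        idx <- nums[seq(1, length(nums), 2)]
        val <- nums[seq(2, length(nums), 2)]
        chg[as.character(idx)] <- val
      }
    }
    charges[[length(charges) + 1]] <- chg
    titles <- c(titles, trimws(r[1]))
  }
  list(charges = charges, titles = titles)
}

# parse one bio3d mol2 record into a molecule (drops explicit hydrogens)
# formal_charges: named integer vector (names = all-atom 1-based indices)
mol2_to_molecule <- function(rec, id, smiles = NULL, formal_charges = NULL) {
  at <- rec$atom
  ty <- at$elety
  elem <- sybyl_element(ty)
  heavy <- which(elem != "H")
  hmap <- match(seq_len(nrow(at)), heavy)    # original -> heavy index
  nh <- integer(length(heavy))
  bonds <- data.frame(i = integer(0), j = integer(0), order = numeric(0))
  if (!is.null(rec$bond) && nrow(rec$bond)) {
    for (b in seq_len(nrow(rec$bond))) {
      o <- rec$bond$origin[b]; t <- rec$bond$target[b]
      ord <- rec$bond$type[b]
      if (elem[o] == "H" || elem[t] == "H") {
        hv <- if (elem[o] == "H") t else o
        if (!is.na(hmap[hv])) nh[hmap[hv]] <- nh[hmap[hv]] + 1L
        next
      }
      ordn <- switch(as.character(ord), "1" = 1, "2" = 2, "3" = 3,
                     "ar" = 1.5, "am" = 1, 1)
      bonds <- rbind(bonds, data.frame(i = hmap[o], j = hmap[t], order = ordn))
    }
  }
  tyh <- ty[heavy]
  arom <- grepl("\\.ar$", tyh) | tyh == "C.cat"
  # formal charges: SYBYL-type inference first (delocalized groups such as
  # carboxylates mark every equivalent atom), then explicit M CHG entries
  # fill in atoms the typing left neutral (e.g. protonated ring nitrogens)
  q <- numeric(length(heavy))
  q[tyh == "N.4"] <- 1
  q[tyh == "O.co2"] <- -0.5
  cat_idx <- which(tyh == "C.cat")  # guanidinium N carries the charge
  for (ci in cat_idx) {
    nb <- unique(c(bonds$j[bonds$i == ci], bonds$i[bonds$j == ci]))
    q[nb[sybyl_element(tyh[nb]) == "N"]] <- 1 / 3
  }
  if (!is.null(formal_charges) && length(formal_charges)) {
    all_idx <- as.integer(names(formal_charges))
    keep <- !is.na(hmap[all_idx]) & q[hmap[all_idx]] == 0
    q[hmap[all_idx[keep]]] <- formal_charges[keep]
  }
  mol <- new_molecule(id = id, elements = elem[heavy],
                      xyz = as.matrix(at[heavy, c("x", "y", "z")]),
                      bonds = bonds, charges = q, aromatic = arom,
                      nH = nh, pcharges = at$charge[heavy], smiles = smiles)
  mol$sybyl <- tyh
  mol
}

#' Parse molecules from SMILES
#'
#' Each SMILES is embedded in 3D with OpenBabel (`--gen3d`), hydrogens are
#' added for typing and then folded into per-heavy-atom counts. Invalid
#' records are skipped and counted. Note that OpenBabel's 3D embedding is
#' not bit-reproducible across runs; pipelines requiring frozen conformers
#' should serialize the embedded library to SDF once and use that file.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional identifiers (default m1, m2, ...).
#' @return List with `molecules` (list of [new_molecule()]) and `n_skipped`.
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  if (!obabel_available()) stop("obabel not found on PATH")
  if (is.null(ids)) ids <- paste0("m", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))
  ids_clean <- gsub("\\s+", "_", ids)
  smifile <- tempfile(fileext = ".smi")
  sdffile <- tempfile(fileext = ".sdf")
  mol2file <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(smifile, sdffile, mol2file)))
  writeLines(paste(smiles, ids_clean), smifile)
  # one 3D embed to SDF (keeps M CHG formal charges), then a cheap
  # coordinate-preserving conversion for SYBYL atom types
  run_obabel(c(smifile, "-O", sdffile, "--gen3d", "-h"))
  run_obabel(c(sdffile, "-O", mol2file))
  mols <- list()
  got <- character(0)
  if (file.exists(mol2file) && file.size(mol2file) > 0) {
    recs <- bio3d::read.mol2(mol2file)
    if (!is.null(recs$atom)) recs <- list(recs)
    chg <- sdf_formal_charges(sdffile)
    for (r in recs) {
      rid <- r$name
      k <- match(rid, ids_clean)
      if (is.na(k)) next
      can <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN",
                        paste0(smiles[k], "\n")), error = function(e) NULL)
      can <- if (!is.null(can)) strsplit(trimws(can), "\\s+")[[1]][1] else smiles[k]
      ci <- match(rid, chg$titles)
      mols[[ids[k]]] <- mol2_to_molecule(r, id = ids[k], smiles = can,
        formal_charges = if (!is.na(ci)) chg$charges[[ci]] else NULL)
      got <- c(got, ids[k])
    }
  }
  skipped <- setdiff(ids, got)
  if (!length(mols)) stop("zero valid records")
  list(molecules = mols, n_skipped = length(skipped), skipped_ids = skipped)
}

#' Parse a compound library from a SMILES or SDF file
#'
#' SMILES files carry one record per line (`SMILES [id]`); SDF files are
#' V2000 with explicit 3D coordinates, which are preserved exactly.
#'
#' @param path File path (`.smi`/`.txt` for SMILES, `.sdf` for SDF).
#' @return As [parse_smiles()]: list with `molecules` and `n_skipped`.
#' @export
parse_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("smi", "txt", "ism")) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("zero valid records")
    parts <- strsplit(trimws(lines), "\\s+")
    smiles <- vapply(parts, `[`, "", 1)
    ids <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1) parts[[i]][2] else paste0("m", i), "")
    parse_smiles(smiles, ids)
  } else if (ext %in% c("sdf", "mol")) {
    parse_sdf(path)
  } else stop("unsupported library format: .", ext)
}

#' Parse an SDF (V2000) library file
#'
#' Coordinates are taken verbatim from the SDF; OpenBabel supplies SYBYL
#' atom types (aromaticity, charge states) and Gasteiger partial charges for
#' the same records.
#'
#' @param path SDF file path.
#' @return As [parse_smiles()].
#' @export
parse_sdf <- function(path) {
  if (!obabel_available()) stop("obabel not found on PATH")
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  valid <- ChemmineR::validSDF(sdfset)
  n_skipped <- sum(!valid)
  sdfset <- sdfset[valid]
  if (length(sdfset) == 0) stop("zero valid records")
  mol2file <- tempfile(fileext = ".mol2")
  on.exit(unlink(mol2file))
  run_obabel(c("-isdf", path, "-O", mol2file, "-h"))
  recs <- bio3d::read.mol2(mol2file)
  if (!is.null(recs$atom)) recs <- list(recs)
  chg <- sdf_formal_charges(path)
  mols <- list()
  ids_seen <- character(0)
  for (k in seq_along(recs)) {
    if (k > length(sdfset)) break
    sdf <- sdfset[[k]]
    id <- ChemmineR::sdfid(sdfset[k])
    if (!nzchar(id) || id %in% ids_seen) id <- paste0("m", k)
    ids_seen <- c(ids_seen, id)
    m <- mol2_to_molecule(recs[[k]], id = id,
      formal_charges = if (k <= length(chg$charges)) chg$charges[[k]] else NULL)
    # overwrite coordinates with the exact SDF values (heavy atoms)
    ab <- ChemmineR::atomblock(sdf)
    el <- gsub("_.*$", "", rownames(ab))
    heavy <- which(toupper(el) != "H")
    if (length(heavy) == n_atoms(m)) m$xyz <- unname(ab[heavy, 1:3, drop = FALSE])
    m$smiles <- tryCatch(
      strsplit(trimws(ChemmineOB::convertFormat("SDF", "CAN",
        paste(ChemmineR::sdf2str(sdf), collapse = "\n"))), "\\s+")[[1]][1],
      error = function(e) NULL)
    mols[[id]] <- m
  }
  list(molecules = mols, n_skipped = n_skipped, skipped_ids = character(0))
}

#' Write molecules to an SDF (V2000) file
#'
#' Heavy atoms only, with current coordinates; optional named properties are
#' written as data fields on every record.
#'
#' @param mols List of [new_molecule()].
#' @param path Output path.
#' @param properties Optional data frame (one row per molecule) of data
#'   fields.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, properties = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(mols)) {
    m <- mols[[k]]
    n <- n_atoms(m); nb <- nrow(m$bonds)
    lines <- c(m$id, "  fragscreen", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    for (a in seq_len(n))
      lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                                m$xyz[a, 1], m$xyz[a, 2], m$xyz[a, 3], m$elements[a]))
    for (b in seq_len(nb)) {
      ord <- m$bonds$order[b]
      lines <- c(lines, sprintf("%3d%3d%3d  0", m$bonds$i[b], m$bonds$j[b],
                                if (ord == 1.5) 4L else as.integer(ord)))
    }
    chg <- which(m$charges != 0 & m$charges == round(m$charges))
    if (length(chg))
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                               paste0(sprintf("%4d%4d", chg, as.integer(m$charges[chg])),
                                      collapse = "")))
    lines <- c(lines, "M  END")
    if (!is.null(properties)) {
      for (p in names(properties))
        lines <- c(lines, sprintf("> <%s>", p), as.character(properties[[p]][k]), "")
    }
    lines <- c(lines, "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}
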