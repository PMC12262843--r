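#' Structure models, subdomain maps and confidence channels
#'
#' A `StructureModel` is a light S3 wrapper around an atom table: one row per
#' atom/bead with chain, residue number, residue name, atom name, coordinates
#' in Angstrom and an optional per-atom confidence (pLDDT, 0-100) read from
#' the PDB B-factor column as structure predictors write it.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `x`, `y`, `z` and optionally `conf`.
#' @param model_id identifier string.
#' @param predictor free-text provenance tag (e.g. the prediction method).
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(atoms, model_id = "model", predictor = "unknown") {
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0L)
    stopf("atom table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stopf("empty model: no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stopf("non-finite coordinates in model '%s'", model_id)
  if (is.null(atoms$conf)) atoms$conf <- NA_real_
  ok <- is.na(atoms$conf) | (atoms$conf >= 0 & atoms$conf <= 100)
  if (!all(ok)) stopf("confidence values outside [0, 100]")
  atoms$chain <- as.character(atoms$chain)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  structure(list(model_id = model_id, predictor = predictor, atoms = atoms),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel '%s' (%s): %d atoms, %d residues, %d chain(s)\n",
              x$model_id, x$predictor, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              length(unique(x$atoms$chain))))
  invisible(x)
}

#' Read a structure model from a PDB file
#'
#' Parses ATOM/HETATM records with fixed PDB columns. The B-factor column is
#' mapped to the per-atom `conf` channel (the pLDDT convention of AlphaFold
#' and kindred predictors); a column of all zeros is treated as "confidence
#' absent". Only the first MODEL of a multi-model file is read; use
#' [read_trajectory_pdb()] for trajectories.
#'
#' @param path PDB file path.
#' @param dialect only `"pdb"` is supported.
#' @param model_id,predictor metadata; `model_id` defaults to the file stem.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, dialect = "pdb",
                           model_id = NULL, predictor = "unknown") {
  dialect <- match.arg(dialect, "pdb")
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1L] - 1L)]
  atoms <- parse_pdb_atoms(lines, path)
  if (nrow(atoms) == 0L) stopf("empty model: no ATOM records in %s", path)
  if (!any(atoms$atom %in% c("CA", "BB")))
    stopf("no C-alpha (or BB bead) atoms in %s", path)
  if (all(atoms$conf == 0)) atoms$conf <- NA_real_
  structure_model(atoms, model_id = model_id %||%
                    sub("\\.[^.]*$", "", basename(path)), predictor = predictor)
}

# Fixed-column ATOM/HETATM parser (PDB v3.3 columns, 1-based):
# name 13-16, resName 18-20, chain 22, resSeq 23-26, x/y/z 31-54, B 61-66.
parse_pdb_atoms <- function(lines, path = "<text>") {
  sel <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  ln <- lines[sel]
  if (length(ln) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), atom = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      conf = numeric()))
  num <- function(s, what, idx) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    if (length(bad) > 0L)
      stopf("malformed %s field in %s at ATOM line %d: '%s'",
            what, path, idx[bad[1L]], s[bad[1L]])
    v
  }
  idx <- which(sel)
  x <- num(substr(ln, 31, 38), "x", idx)
  y <- num(substr(ln, 39, 46), "y", idx)
  z <- num(substr(ln, 47, 54), "z", idx)
  resno <- num(substr(ln, 23, 26), "residue-number", idx)
  if (any(!is.finite(x) | !is.finite(y) | !is.finite(z) | !is.finite(resno)))
    stopf("missing coordinate/residue fields in %s", path)
  bf <- substr(ln, 61, 66)
  conf <- suppressWarnings(as.numeric(bf))
  conf[is.na(conf)] <- 0
  data.frame(chain = trimws(substr(ln, 22, 22)),
             resno = as.integer(resno),
             resname = trimws(substr(ln, 18, 20)),
             atom = trimws(substr(ln, 13, 16)),
             x = x, y = y, z = z, conf = conf)
}

#' Write a structure model as a PDB file
#'
#' Coordinates are written at PDB precision (%8.3f); confidence goes to the
#' B-factor column (0.00 when absent).
#'
#' @param model a [structure_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  conf <- ifelse(is.na(a$conf), 0, a$conf)
  name4 <- ifelse(nchar(a$atom) < 4L, sprintf(" %-3s", a$atom),
                  sprintf("%-4s", a$atom))
  chain <- ifelse(nzchar(a$chain), substr(a$chain, 1, 1), "A")
  lines <- sprintf(
    "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(a)) %% 100000L, name4, substr(a$resname, 1, 3), chain,
    a$resno %% 10000L, a$x, a$y, a$z, 1, conf)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Build and validate a subdomain map
#'
#' Residue intervals for the transmembrane-region subdomains. Intervals are
#' 1-based half-open `[start, end)`: a boundary residue belongs to exactly one
#' subdomain (the later helix claims a shared start). The hairpins are derived
#' unions: HP1 = TM1 u TM2 and HP2 = TM3 u TM4.
#'
#' @param boundaries named list of length-2 numeric vectors `c(start, end)`.
#'   Names must come from APH1, TM0, TM1, TM2, APH2, TM3, TM4; TM1..TM4 are
#'   required.
#' @param policy only `"half_open"` is supported.
#' @param tmr_interval the enclosing transmembrane-region interval.
#' @return A `SubdomainMap` with `$intervals`, `$HP1`, `$HP2`, `$tmr_interval`.
#' @export
make_subdomain_map <- function(boundaries = default_tm_boundaries(),
                               policy = "half_open",
                               tmr_interval = c(550, 777)) {
  match.arg(policy, "half_open")
  allowed <- c("APH1", "TM0", "TM1", "TM2", "APH2", "TM3", "TM4")
  bad <- setdiff(names(boundaries), allowed)
  if (length(bad) > 0L)
    stopf("unknown subdomain name(s): %s", paste(bad, collapse = ", "))
  need <- setdiff(c("TM1", "TM2", "TM3", "TM4"), names(boundaries))
  if (length(need) > 0L)
    stopf("missing TM interval(s): %s", paste(need, collapse = ", "))
  for (nm in names(boundaries)) {
    iv <- boundaries[[nm]]
    if (!is_interval(iv)) stopf("%s: interval must be numeric c(start, end)", nm)
    if (iv[2L] <= iv[1L]) stopf("%s: empty or inverted interval [%s, %s)",
                                nm, iv[1L], iv[2L])
    if (iv[1L] < tmr_interval[1L] || iv[2L] > tmr_interval[2L])
      stopf("%s: interval outside the TMR interval [%d, %d)",
            nm, tmr_interval[1L], tmr_interval[2L])
  }
  tm <- lapply(c("TM1", "TM2", "TM3", "TM4"), function(nm) boundaries[[nm]])
  for (i in 1:3) {
    if (tm[[i + 1L]][1L] < tm[[i]][2L])
      stopf("TM intervals out of order or overlapping: TM%d [%s,%s) vs TM%d [%s,%s)",
            i, tm[[i]][1L], tm[[i]][2L], i + 1L, tm[[i + 1L]][1L], tm[[i + 1L]][2L])
  }
  structure(list(
    intervals = boundaries,
    HP1 = c(boundaries$TM1[1L], boundaries$TM2[2L]),
    HP2 = c(boundaries$TM3[1L], boundaries$TM4[2L]),
    tmr_interval = tmr_interval
  ), class = "SubdomainMap")
}

#' Default transmembrane-helix boundaries
#'
#' The MCTP4-style defaults: TM1 `[600,615)`, TM2 `[615,636)`, TM3 `[715,736)`,
#' TM4 `[736,751)`. HP1 then spans residues 600-635 inclusive and HP2 spans
#' 715-750 inclusive.
#' @return Named list of intervals, suitable for [make_subdomain_map()].
#' @export
default_tm_boundaries <- function() {
  list(TM1 = c(600, 615), TM2 = c(615, 636),
       TM3 = c(715, 736), TM4 = c(736, 751))
}

#' @export
print.SubdomainMap <- function(x, ...) {
  cat("SubdomainMap (half-open [start, end)):\n")
  for (nm in names(x$intervals))
    cat(sprintf("  %-5s [%d, %d)\n", nm, x$intervals[[nm]][1L], x$intervals[[nm]][2L]))
  cat(sprintf("  HP1   [%d, %d)   HP2   [%d, %d)\n",
              x$HP1[1L], x$HP1[2L], x$HP2[1L], x$HP2[2L]))
  invisible(x)
}

#' Per-residue confidence (pLDDT) profile of a region
#'
#' Takes the confidence of the C-alpha atom (or the BB bead for coarse-grained
#' models) of every residue of `region` present in the model. Models without a
#' confidence channel are refused rather than imputed.
#'
#' @param model a [structure_model()] carrying confidence values.
#' @param region half-open residue interval `c(start, end)`.
#' @param chain chain to profile (default first chain).
#' @return data.frame with columns `resno`, `plddt`.
#' @export
extract_confidence <- function(model, region, chain = NULL) {
  a <- model$atoms
  chain <- chain %||% a$chain[1L]
  a <- a[a$chain == chain & a$atom %in% c("CA", "BB"), , drop = FALSE]
  a <- a[a$resno >= region[1L] & a$resno < region[2L], , drop = FALSE]
  if (nrow(a) == 0L)
    stopf("no residues of [%s, %s) present in model '%s' chain %s",
          region[1L], region[2L], model$model_id, chain)
  if (all(is.na(a$conf)))
    stopf("model '%s' carries no confidence channel", model$model_id)
  a <- a[!duplicated(a$resno), , drop = FALSE]
  data.frame(resno = a$resno, plddt = a$conf)
}

#' Read a predicted-aligned-error (PAE) matrix from JSON
#'
#' Accepts the common dialects: a bare nested-list matrix, an object (or
#' one-element array of objects) with key `predicted_aligned_error` or `pae`
#' holding either a nested-list matrix or a flat list of length n^2
#' (row-major).
#'
#' @param path JSON file.
#' @return An `n x n` matrix of expected position errors (Angstrom).
#' @export
read_pae <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  payload <- obj
  if (is.list(payload) && !is.null(names(payload))) {
    key <- intersect(c("predicted_aligned_error", "pae"), names(payload))
    if (length(key) == 0L) stopf("no PAE payload found in %s", path)
    payload <- payload[[key[1L]]]
  } else if (is.list(payload) && is.null(names(payload)) && length(payload) == 1L) {
    return(read_pae_payload(payload[[1L]], path))
  }
  read_pae_payload(payload, path)
}

read_pae_payload <- function(payload, path) {
  if (is.list(payload) && !is.null(names(payload))) {
    key <- intersect(c("predicted_aligned_error", "pae"), names(payload))
    if (length(key) > 0L) payload <- payload[[key[1L]]]
  }
  if (is.list(payload)) payload <- do.call(rbind, lapply(payload, as.numeric))
  if (is.matrix(payload)) {
    m <- payload
  } else {
    v <- as.numeric(payload)
    n <- sqrt(length(v))
    if (n != round(n)) stopf("flat PAE payload of length %d is not square", length(v))
    m <- matrix(v, nrow = n, byrow = TRUE)
  }
  if (nrow(m) != ncol(m)) stopf("PAE payload in %s is not square (%d x %d)",
                                path, nrow(m), ncol(m))
  if (any(m < 0)) stopf("negative PAE entries in %s", path)
  m
}

#' Per-chain-pair PAE block statistics
#'
#' Splits a PAE matrix into chain blocks and reports the mean and minimum
#' expected error of each ordered block (A,A), (A,B), (B,A), (B,B), ... Low
#' inter-chain blocks indicate a confidently predicted interface.
#'
#' @param pae square PAE matrix.
#' @param chain_lengths named integer vector of residues per chain, in matrix
#'   order.
#' @return data.frame with columns `chain_i`, `chain_j`, `mean`, `min`.
#' @export
pae_block_stats <- function(pae, chain_lengths) {
  if (sum(chain_lengths) != nrow(pae))
    stopf("chain lengths sum to %d but PAE is %d x %d",
          sum(chain_lengths), nrow(pae), ncol(pae))
  nms <- names(chain_lengths) %||% LETTERS[seq_along(chain_lengths)]
  ends <- cumsum(chain_lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- expand.grid(chain_i = nms, chain_j = nms,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(match(out$chain_i, nms), match(out$chain_j, nms)), ]
  out$mean <- NA_real_
  out$min <- NA_real_
  for (r in seq_len(nrow(out))) {
    i <- match(out$chain_i[r], nms)
    j <- match(out$chain_j[r], nms)
    blk <- pae[starts[i]:ends[i], starts[j]:ends[j], drop = FALSE]
    out$mean[r] <- mean(blk)
    out$min[r] <- min(blk)
  }
  rownames(out) <- NULL
  out
}
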