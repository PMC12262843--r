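#' Rigid-body superposition and pairwise RMSD matrices
#'
#' @name superposition
NULL

#' Extract a residue interval from a structure model
#'
#' @param model a [structure_model()].
#' @param interval half-open residue interval `c(start, end)`.
#' @param chain optional chain restriction.
#' @return A submodel with exactly the residues of the interval, coordinates
#'   unchanged.
#' @export
extract_region <- function(model, interval, chain = NULL) {
  a <- model$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  a <- a[a$resno >= interval[1L] & a$resno < interval[2L], , drop = FALSE]
  if (nrow(a) == 0L)
    stopf("no residues of [%s, %s) present in model '%s'",
          interval[1L], interval[2L], model$model_id)
  structure_model(a, model_id = model$model_id, predictor = model$predictor)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets via the SVD of the cross-covariance matrix. A
#' reflection-requiring degenerate case is resolved by flipping the sign of
#' the smallest singular direction, keeping det(R) = +1.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`, paired rows.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) such
#'   that `mobile %*% rotation + translation` superposes onto `reference`, and
#'   the minimised `rmsd` in Angstrom.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stopf("point counts differ: %d vs %d", nrow(mobile), nrow(reference))
  if (nrow(mobile) < 3L) stopf("need at least 3 points, got %d", nrow(mobile))
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2L, cm); Q <- sweep(reference, 2L, cr)
  sv <- svd(crossprod(P, Q))                 # H = P' Q = U D V'
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v) # mobile-row rotation
  fitted <- P %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd)
}

# C-alpha (or CG backbone bead) coordinates of one residue set, ordered by
# residue number; errors if a requested residue is absent.
ca_coords <- function(model, residues = NULL, chain = NULL) {
  a <- model$atoms
  chain <- chain %||% a$chain[1L]
  a <- a[a$chain == chain & a$atom %in% c("CA", "BB"), , drop = FALSE]
  a <- a[!duplicated(a$resno), , drop = FALSE]
  if (!is.null(residues)) {
    miss <- setdiff(residues, a$resno)
    if (length(miss) > 0L)
      stopf("model '%s': missing residue(s) %s", model$model_id,
            paste(utils::head(miss, 8L), collapse = ", "))
    a <- a[match(residues, a$resno), , drop = FALSE]
  } else {
    a <- a[order(a$resno), , drop = FALSE]
  }
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$resno
  m
}

#' Pairwise Kabsch RMSD matrix over a model ensemble
#'
#' Each entry is the minimum C-alpha RMSD of a model pair after independent
#' least-squares superposition of the selected region. Models that disagree on
#' residue coverage are compared on the intersection of their residue sets
#' (reported in the result); for multimers chain A is used unless `chain`
#' says otherwise.
#'
#' @param models list of [structure_model()]s.
#' @param region half-open residue interval, or `NULL` for whole models.
#' @param selection atom selection; only `"CA"` (C-alpha / BB bead).
#' @param chain chain identifier used for every model (default: each model's
#'   first chain).
#' @param min_shared minimum number of shared residues required.
#' @return list of class `RMSDMatrix`: `$rmsd` (symmetric matrix with model-id
#'   dimnames), `$region`, `$selection`, `$residues` (shared residue numbers).
#' @export
pairwise_rmsd_matrix <- function(models, region = NULL, selection = "CA",
                                 chain = NULL, min_shared = 10L) {
  match.arg(selection, "CA")
  if (length(models) < 2L) stopf("need at least 2 models")
  ids <- vapply(models, function(m) m$model_id, character(1L))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  per_res <- lapply(models, function(m) {
    a <- m$atoms
    ch <- chain %||% a$chain[1L]
    a <- a[a$chain == ch & a$atom %in% c("CA", "BB"), , drop = FALSE]
    if (!is.null(region))
      a <- a[a$resno >= region[1L] & a$resno < region[2L], , drop = FALSE]
    a[!duplicated(a$resno), , drop = FALSE]
  })
  shared <- Reduce(intersect, lapply(per_res, function(a) a$resno))
  if (length(shared) < min_shared) {
    all_res <- sort(unique(unlist(lapply(per_res, function(a) a$resno))))
    stopf("only %d shared residue(s) across models (need >= %d); non-universal: %s",
          length(shared), min_shared,
          paste(utils::head(setdiff(all_res, shared), 10L), collapse = ", "))
  }
  shared <- sort(shared)
  coords <- lapply(per_res, function(a) {
    as.matrix(a[match(shared, a$resno), c("x", "y", "z")])
  })
  n <- length(models)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd
    M[i, j] <- M[j, i] <- r
  }
  structure(list(rmsd = M,
                 region = if (is.null(region)) "whole" else
                   sprintf("[%s,%s)", region[1L], region[2L]),
                 selection = selection, residues = shared),
            class = "RMSDMatrix")
}

#' @export
print.RMSDMatrix <- function(x, ...) {
  cat(sprintf("RMSDMatrix: region %s, selection %s, %d shared residues\n",
              x$region, x$selection, length(x$residues)))
  print(round(x$rmsd, 2))
  invisible(x)
}

#' Write an RMSD matrix as TSV with a JSON metadata sidecar
#' @param x an `RMSDMatrix`.
#' @param path output TSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_rmsd_matrix <- function(x, path) {
  df <- data.frame(model = rownames(x$rmsd), x$rmsd, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(region = x$region, selection = x$selection,
                            n_residues = length(x$residues)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
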