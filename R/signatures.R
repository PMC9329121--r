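#' Construct a reference signature set
#'
#' A reference signature set is a 96 x k matrix of channel probabilities
#' (COSMIC-style SBS signatures): every column is non-negative and sums to 1.
#'
#' @param matrix numeric 96 x k matrix; row names must be (or are set to)
#'   the canonical 96-channel labels
#' @param names signature names (default: column names)
#' @return a `signature_set` (the validated matrix)
#' @export
signature_set <- function(matrix, names = colnames(matrix)) {
  m <- as.matrix(matrix)
  if (nrow(m) != 96)
    stop(errorCondition("signature matrix must have 96 rows",
                        class = c("apomut_bad_signatures", "error")))
  if (any(m < 0))
    stop(errorCondition("signature probabilities must be non-negative",
                        class = c("apomut_bad_signatures", "error")))
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    stop(errorCondition("every signature column must sum to 1",
                        class = c("apomut_bad_signatures", "error")))
  if (is.null(rownames(m))) rownames(m) <- channels(96)
  if (!setequal(rownames(m), channels(96)))
    stop(errorCondition("row names must be the 96 channel labels",
                        class = c("apomut_bad_signatures", "error")))
  m <- m[channels(96), , drop = FALSE]
  colnames(m) <- names
  structure(m, class = c("signature_set", class(m)))
}

#' Read / write COSMIC-format signature tables
#'
#' TSV with a channel label column (`Type`/`MutationType`, `A[C>A]A` style)
#' and one column per signature.
#'
#' @param path file path
#' @return a `signature_set` (reader); `path` invisibly (writer)
#' @export
read_signatures <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  lab_col <- intersect(c("Type", "MutationType", "MutationsType"),
                       names(df))[1]
  if (is.na(lab_col))
    stop(errorCondition("no channel label column (Type/MutationType)",
                        class = c("apomut_bad_signatures", "error")))
  m <- as.matrix(df[, setdiff(names(df), lab_col), drop = FALSE])
  rownames(m) <- df[[lab_col]]
  signature_set(m)
}

#' @rdname read_signatures
#' @param refs a `signature_set`
#' @export
write_signatures <- function(refs, path) {
  df <- data.frame(MutationType = rownames(refs),
                   unclass(refs)[, , drop = FALSE], check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cosine similarity between two non-negative vectors
#' @param u,v numeric vectors of equal length, at least one nonzero entry
#'   each
#' @return `sum(u*v) / (||u|| ||v||)`, in \[0, 1\] for non-negative inputs
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop(errorCondition("cosine similarity undefined for a zero vector",
                        class = c("apomut_zero_vector", "error")))
  sum(u * v) / (nu * nv)
}

## Lawson-Hanson active-set non-negative least squares: min ||A x - b||, x>=0
nnls_solve <- function(A, b, tol = 1e-10, max_iter = 10 * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0
  while (any(!passive & w > tol) && iter < max_iter * 10) {
    iter <- iter + 1
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      z <- numeric(n)
      z[passive] <- qr.coef(qr(Ap), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

fit_cosine <- function(refs, support, catalog) {
  if (!length(support)) return(list(cos = -Inf, act = numeric(0)))
  act <- nnls_solve(refs[, support, drop = FALSE], catalog)
  recon <- refs[, support, drop = FALSE] %*% act
  cos <- if (sum(recon^2) == 0) 0 else cosine_similarity(catalog, recon)
  list(cos = cos, act = act, recon = as.numeric(recon))
}

#' Penalized non-negative refitting of a catalogue onto reference signatures
#'
#' Sparse forward-backward selection with non-negative least squares on the
#' selected support. Starting from the single signature of highest cosine
#' similarity to the catalogue, a candidate signature is added only when it
#' improves the reconstruction cosine by more than `add_penalty`; after each
#' addition, any selected signature whose removal costs less than
#' `remove_penalty` in cosine is dropped. The procedure is deterministic
#' (ties broken by signature order) and the penalties act as
#' cosine-improvement thresholds.
#'
#' The default pair 0.005/0.001 is the sensitive ("lowered-penalty") setting
#' used for per-sample activity calls; the stricter default-discovery pair
#' 0.05/0.01 can be requested via the arguments and reported side by side.
#'
#' @param catalog_vector numeric vector of 96 non-negative channel counts
#' @param refs a `signature_set`
#' @param add_penalty minimum cosine improvement to accept a signature
#'   (default 0.005)
#' @param remove_penalty maximum cosine loss at which a selected signature
#'   is discarded as redundant (default 0.001)
#' @return a `signature_activity`: list with `activities` (named
#'   non-negative mutation counts over all reference signatures),
#'   `reconstruction` (96-vector), `residual_cosine`, `penalty_mode`
#'   (`"lowered"` for the default pair, `"default"` for 0.05/0.01,
#'   `"custom"` otherwise), `add_penalty`, `remove_penalty`
#' @export
nnls_refit <- function(catalog_vector, refs, add_penalty = 0.005,
                       remove_penalty = 0.001) {
  if (ncol(refs) == 0)
    stop(errorCondition("empty reference signature set",
                        class = c("apomut_bad_signatures", "error")))
  k <- ncol(refs)
  total <- sum(catalog_vector)
  mode <- if (isTRUE(all.equal(c(add_penalty, remove_penalty),
                               c(0.005, 0.001)))) "lowered"
          else if (isTRUE(all.equal(c(add_penalty, remove_penalty),
                                    c(0.05, 0.01)))) "default"
          else "custom"
  empty <- structure(list(
    activities = setNames(numeric(k), colnames(refs)),
    reconstruction = numeric(96), residual_cosine = NA_real_,
    penalty_mode = mode, add_penalty = add_penalty,
    remove_penalty = remove_penalty), class = "signature_activity")
  if (total == 0) return(empty)

  sims <- apply(unclass(refs), 2, cosine_similarity, v = catalog_vector)
  support <- which.max(sims)
  fit <- fit_cosine(refs, support, catalog_vector)
  seen <- character(0)
  repeat {
    state <- paste(sort(support), collapse = ",")
    if (state %in% seen) break
    seen <- c(seen, state)
    changed <- FALSE
    ## forward: best single addition, if it clears the add penalty
    candidates <- setdiff(seq_len(k), support)
    if (length(candidates)) {
      gains <- vapply(candidates, function(j)
        fit_cosine(refs, c(support, j), catalog_vector)$cos - fit$cos,
        numeric(1))
      best <- which.max(gains)
      if (gains[best] > add_penalty) {
        support <- sort(c(support, candidates[best]))
        fit <- fit_cosine(refs, support, catalog_vector)
        changed <- TRUE
      }
    }
    ## backward: drop any signature whose removal is nearly free
    repeat {
      if (length(support) <= 1) break
      losses <- vapply(support, function(j)
        fit$cos - fit_cosine(refs, setdiff(support, j), catalog_vector)$cos,
        numeric(1))
      worst <- which.min(losses)
      if (losses[worst] < remove_penalty) {
        support <- setdiff(support, support[worst])
        fit <- fit_cosine(refs, support, catalog_vector)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  act <- setNames(numeric(k), colnames(refs))
  act[support] <- fit$act
  ## keep total attributed mutations within the catalogue total
  if (sum(act) > total * (1 + 1e-6)) {
    act <- act * total / sum(act)
    fit$recon <- as.numeric(unclass(refs) %*% act)
  }
  structure(list(activities = act,
                 reconstruction = fit$recon,
                 residual_cosine = fit$cos,
                 penalty_mode = mode,
                 add_penalty = add_penalty,
                 remove_penalty = remove_penalty),
            class = "signature_activity")
}

#' @export
print.signature_activity <- function(x, ...) {
  nz <- x$activities[x$activities > 0]
  cat("<signature_activity> cosine=",
      format(x$residual_cosine, digits = 4),
      " mode=", x$penalty_mode, "\n", sep = "")
  if (length(nz)) print(round(nz, 1))
  invisible(x)
}

#' Decompose a signature profile into a mixture of reference signatures
#'
#' Finds the non-negative mixture of reference signatures minimizing the
#' reconstruction error to a 96-channel probability profile (for example a
#' de novo extracted signature), and grades the decomposition by cosine
#' similarity: above 0.97 the profile is explained by known signatures
#' (`decomposed`), below 0.95 it probably represents a new signature
#' (`novel`), in between `ambiguous`.
#'
#' @param denovo_vector numeric vector of 96 channel probabilities (sums
#'   to 1)
#' @param refs a `signature_set`
#' @return list with `weights` (mixture weights over the references,
#'   normalized to sum 1), `cosine`, `status`
#' @export
decompose_signature <- function(denovo_vector, refs) {
  if (ncol(refs) == 0)
    stop(errorCondition("empty reference signature set",
                        class = c("apomut_bad_signatures", "error")))
  if (abs(sum(denovo_vector) - 1) > 1e-6)
    stop(errorCondition("de novo signature must sum to 1",
                        class = c("apomut_bad_signatures", "error")))
  x <- nnls_solve(unclass(refs), denovo_vector)
  recon <- as.numeric(unclass(refs) %*% x)
  cos <- if (sum(recon^2) == 0) 0 else
    cosine_similarity(denovo_vector, recon)
  w <- if (sum(x) > 0) x / sum(x) else x
  status <- if (cos > 0.97) "decomposed"
            else if (cos < 0.95) "novel" else "ambiguous"
  list(weights = setNames(w, colnames(refs)), cosine = cos, status = status)
}

#' Write per-sample signature activities as TSV
#' @param activities named list of `signature_activity` (names = samples) or
#'   a sample x signature numeric matrix
#' @param path output path
#' @return `path` invisibly
#' @export
write_activities <- function(activities, path) {
  m <- if (is.matrix(activities)) activities
       else do.call(rbind, lapply(activities, function(a) a$activities))
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  if (is.null(rownames(m)) && is.list(activities))
    rownames(m) <- names(activities)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
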