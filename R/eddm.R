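# Ensemble difference distance matrix (EDDM) analysis: per-residue-pair
# distance distributions of two conformational ensembles, long-distance
# masking, and dual-threshold Wilcoxon significance.

#' Per-conformation residue--residue distances of an ensemble
#'
#' @param ens an `ensemble` (see [simulate_ensemble_pair()] or
#'   [read_ensemble_pdb()]).
#' @param mode distance mode; `"CA"` uses the stored (C-alpha) coordinates.
#'   For single-atom-per-residue ensembles `"closest-heavy-atom"` is
#'   identical to `"CA"`.
#' @return a `distance_ensemble`: list with `distances` (conformations x
#'   pairs matrix, Angstrom), `pair_index` (tibble `pair`, `i`, `j`),
#'   `mode`, `n_res`.
#' @export
residue_distance_ensemble <- function(ens, mode = c("CA", "closest-heavy-atom")) {
  mode <- match.arg(mode)
  if (!inherits(ens, "ensemble")) abort("`ens` must be an ensemble object")
  co <- ens$coords
  d <- dim(co)
  if (length(d) != 3L || d[1] < 2L) abort("ensemble needs >= 2 conformations")
  if (anyNA(co)) {
    bad <- unique(which(apply(is.na(co), 2L, any)))
    abort(paste("missing coordinates for residues:",
                paste(ens$residue_labels[bad], collapse = ", ")))
  }
  n_conf <- d[1]; n_res <- d[2]
  pairs <- which(upper.tri(matrix(0, n_res, n_res)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  dist_mat <- matrix(0, n_conf, nrow(pairs))
  idx <- cbind(pairs[, 1L], pairs[, 2L])
  for (c_ in seq_len(n_conf)) {
    dmat <- as.matrix(stats::dist(co[c_, , ]))
    dist_mat[c_, ] <- dmat[idx]
  }
  structure(list(distances = dist_mat,
                 pair_index = tibble(pair = seq_len(nrow(pairs)),
                                     i = pairs[, 1L], j = pairs[, 2L]),
                 residue_labels = ens$residue_labels,
                 state_label = ens$state_label,
                 mode = mode, n_res = n_res),
            class = "distance_ensemble")
}

#' @export
print.distance_ensemble <- function(x, ...) {
  cat("<distance_ensemble> ", nrow(x$distances), " conformations x ",
      ncol(x$distances), " pairs (", x$mode, ")\n", sep = "")
  invisible(x)
}

#' Mask long distances
#'
#' Replaces every distance by `min(distance, cap)`: differences between
#' short distances are kept intact while differences between long
#' distances are reduced (and vanish once both exceed the cap).
#'
#' @param de a `distance_ensemble`.
#' @param cap masking cap, Angstrom.
#' @return the masked `distance_ensemble`.
#' @export
mask_distances <- function(de, cap = 10) {
  if (!inherits(de, "distance_ensemble")) abort("`de` must be a distance_ensemble")
  .check_scalar(cap, "cap", min = 0, allow_min = FALSE)
  de$distances <- pmin(de$distances, cap)
  de$cap <- cap
  de
}

#' Ensemble difference distance matrix comparison
#'
#' For each residue pair, compares the masked distance distributions of
#' two ensembles with a two-sample Wilcoxon rank-sum test and computes the
#' average masked distance difference (state A minus state B). A pair is
#' significant when `p < p_thresh` and `|mean difference| > diff_thresh`
#' (the dual threshold; no further multiplicity correction is applied).
#'
#' @param a,b `distance_ensemble` objects (or `ensemble` objects, which
#'   are converted with [residue_distance_ensemble()]) sharing the same
#'   pair index; >= 30 conformations each (400 is the reference ensemble
#'   size).
#' @param p_thresh Wilcoxon p-value threshold (default 1e-5).
#' @param diff_thresh masked-difference threshold, Angstrom (default 1).
#' @param cap masking cap, Angstrom (default 10).
#' @param exact_max use the exact Wilcoxon distribution when both
#'   ensembles have fewer conformations than this.
#' @return an `eddm_result`: tibble (`i`, `j`, `mean_diff`, `p`,
#'   `significant`) with thresholds attached.
#' @export
eddm_compare <- function(a, b, p_thresh = 1e-5, diff_thresh = 1, cap = 10,
                         exact_max = 50) {
  if (inherits(a, "ensemble")) a <- residue_distance_ensemble(a)
  if (inherits(b, "ensemble")) b <- residue_distance_ensemble(b)
  if (!identical(a$pair_index[c("i", "j")], b$pair_index[c("i", "j")])) {
    abort("mismatched residue sets between the two ensembles")
  }
  na <- nrow(a$distances); nb <- nrow(b$distances)
  if (na < 30 || nb < 30) abort("need >= 30 conformations per ensemble")
  da <- pmin(a$distances, cap)
  db <- pmin(b$distances, cap)
  n_pair <- ncol(da)
  exact <- max(na, nb) < exact_max

  p <- numeric(n_pair)
  if (exact) {
    for (k in seq_len(n_pair)) {
      # masking introduces ties; wilcox.test then falls back to the
      # normal approximation, which is the intended behaviour
      p[k] <- suppressWarnings(
        wilcox.test(da[, k], db[, k], exact = TRUE)$p.value)
    }
  } else {
    # normal approximation with tie correction, vectorised over pairs
    N <- na + nb
    ranks <- apply(rbind(da, db), 2L, rank)
    W <- colSums(ranks[seq_len(na), , drop = FALSE]) - na * (na + 1) / 2
    tie_term <- apply(rbind(da, db), 2L, function(col) {
      tt <- table(col); sum(tt^3 - tt)
    })
    mu <- na * nb / 2
    sigma <- sqrt(na * nb / 12 * ((N + 1) - tie_term / (N * (N - 1))))
    z <- (W - mu - sign(W - mu) * 0.5) / pmax(sigma, .Machine$double.eps)
    p <- 2 * pnorm(-abs(z))
  }
  mean_diff <- colMeans(da) - colMeans(db)
  out <- a$pair_index
  out$mean_diff <- mean_diff
  out$p <- p
  out$significant <- p < p_thresh & abs(mean_diff) > diff_thresh
  out <- as_tibble(out)
  class(out) <- c("eddm_result", class(out))
  attr(out, "thresholds") <- c(p = p_thresh, diff = diff_thresh, cap = cap)
  attr(out, "residue_labels") <- a$residue_labels
  attr(out, "n_conf") <- c(a = na, b = nb)
  out
}

#' @export
print.eddm_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf("<eddm_result> %d pairs, %d significant (p < %g and |diff| > %g A, cap %g A)\n",
              nrow(x), sum(x$significant), th[["p"]], th[["diff"]],
              th[["cap"]]))
  NextMethod()
}

#' Symmetric matrix of masked mean distance differences
#'
#' @param x an `eddm_result`.
#' @param what `"mean_diff"`, `"p"`, or `"significant"`.
#' @return a symmetric matrix keyed by residue.
#' @export
eddm_matrix <- function(x, what = c("mean_diff", "p", "significant")) {
  what <- match.arg(what)
  n <- max(x$j)
  m <- matrix(if (what == "p") NA_real_ else 0, n, n)
  v <- as.numeric(x[[what]])
  m[cbind(x$i, x$j)] <- v
  m[cbind(x$j, x$i)] <- v
  labs <- attr(x, "residue_labels")
  if (!is.null(labs)) dimnames(m) <- list(labs, labs)
  m
}

#' Annotate EDDM pairs with secondary-structure elements
#'
#' Joins an annotation table (residue ranges named by structural element,
#' e.g. beta9, alpha4) to an EDDM result so significant pairs can be
#' reported in a grid keyed by element.
#'
#' @param x an `eddm_result`.
#' @param annotation data frame with columns `element`, `from`, `to`
#'   (residue indices, inclusive).
#' @return the result with `element_i` and `element_j` columns.
#' @export
eddm_annotate <- function(x, annotation) {
  annotation <- as_tibble(annotation)
  if (!all(c("element", "from", "to") %in% names(annotation))) {
    abort("`annotation` needs columns element, from, to")
  }
  lab <- function(res) {
    hit <- annotation$element[annotation$from <= res & annotation$to >= res]
    if (length(hit)) hit[1] else NA_character_
  }
  x$element_i <- vapply(x$i, lab, character(1))
  x$element_j <- vapply(x$j, lab, character(1))
  x
}

# ---- multi-model PDB input/output -----------------------------------------

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL block per conformation, C-alpha atoms only.
#'
#' @param ens an `ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  co <- ens$coords
  d <- dim(co)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   kinforce ensemble state %s", ens$state_label), con)
  for (m in seq_len(d[1])) {
    writeLines(sprintf("MODEL     %4d", m), con)
    lines <- sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(d[2]), seq_len(d[2]),
      co[m, , 1L], co[m, , 2L], co[m, , 3L])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as an ensemble
#'
#' Accepts C-alpha-only chains, one MODEL per conformation, via a minimal
#' fixed-width ATOM reader.
#'
#' @param path PDB file.
#' @param state_label label for the ensemble.
#' @return an `ensemble` object.
#' @export
read_ensemble_pdb <- function(path, state_label = basename(path)) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) model_starts <- 0L
  atoms <- grepl("^ATOM", lines) & substr(lines, 13, 16) == " CA "
  model_id <- findInterval(seq_along(lines), model_starts)
  keep <- which(atoms)
  if (length(keep) == 0) abort("no CA ATOM records found")
  xyz <- cbind(as.numeric(substr(lines[keep], 31, 38)),
               as.numeric(substr(lines[keep], 39, 46)),
               as.numeric(substr(lines[keep], 47, 54)))
  mid <- model_id[keep]
  n_conf <- length(unique(mid))
  n_res <- sum(mid == mid[1])
  if (any(table(mid) != n_res)) abort("models differ in residue count")
  co <- array(NA_real_, c(n_conf, n_res, 3L))
  for (m in seq_len(n_conf)) {
    co[m, , ] <- xyz[mid == unique(mid)[m], , drop = FALSE]
  }
  structure(list(coords = co, residue_labels = paste0("R", seq_len(n_res)),
                 state_label = state_label),
            class = "ensemble")
}
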