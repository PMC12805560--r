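#' Embed a random 3D conformer for a molecular graph
#'
#' SMILES carries connectivity but no geometry, so a 3D arrangement has to be
#' generated. The embedder is a seeded distance-geometry procedure:
#'
#' 1. topological (bond-count) distances are scaled to rough Angstrom
#'    distances and embedded in 3D by classical multidimensional scaling;
#' 2. seeded Gaussian jitter breaks planar/collinear degeneracies;
#' 3. the coordinates are refined by minimizing a sum of pairwise harmonic
#'    terms — bond lengths at the sum of covalent radii (shortened for
#'    double/triple bonds), 1-3 distances encoding ideal angles from the
#'    central atom's coordination, and one-sided repulsion keeping
#'    non-bonded atoms apart;
#' 4. a seeded random rotation orients the model, and the centroid is moved
#'    to the origin.
#'
#' Identical `(graph, seed)` reproduce bit-identical coordinates; different
#' seeds give different conformations and orientations, mirroring the
#' click-to-click variation of the interactive generator. If a refined
#' geometry violates the distance sanity checks, the embedder retries with
#' derived seeds.
#'
#' @param graph A hydrogen-explicit `molecule_graph` (heavy-atom graphs are
#'   accepted too, e.g. under the no-hydrogens rendering mode).
#' @param seed Integer seed.
#' @param max_retries Number of derived-seed retries before giving up.
#' @return A `conformer`: list with `coords` (n x 3 matrix, Angstrom,
#'   index-aligned with `graph$atoms`) and `seed`.
#' @examples
#' g <- add_hydrogens(parse_smiles("C1CCCCC1"))
#' conf <- embed_conformer(g, seed = 7)
#' dim(conf$coords) # 18 x 3
#' @export
embed_conformer <- function(graph, seed = 0L, max_retries = 10L) {
  stopifnot(inherits(graph, "molecule_graph"))
  seed <- as.integer(seed)
  for (k in 0:max_retries) {
    seed_k <- (abs(seed) + k * 1000003L) %% 2147483647L
    coords <- embed_once(graph, seed_k)
    if (conformer_valid(graph, coords)) {
      return(structure(list(coords = coords, seed = seed), class = "conformer"))
    }
  }
  abort_mf("molforge_embedding_failure", sprintf(
    "failed to embed %s after %d attempts",
    dQuote(graph$source_smiles, q = FALSE), max_retries + 1L))
}

embed_once <- function(graph, seed) {
  n <- nrow(graph$atoms)
  if (n == 1L) return(matrix(0, 1, 3))

  topo <- topo_distances(graph)
  pairs <- build_pair_terms(graph, topo)

  with_seed(seed, {
    # MDS on scaled topological distances gives an untangled starting shape;
    # jitter breaks the planarity of rings and chains.
    d0 <- topo * 1.45
    mds <- suppressWarnings(stats::cmdscale(stats::as.dist(d0), k = min(3L, n - 1L)))
    X <- matrix(0, n, 3)
    if (ncol(mds) > 0) X[, seq_len(ncol(mds))] <- mds
    X <- X + matrix(stats::rnorm(3 * n, sd = 0.25), n, 3)

    X <- refine_coords(X, pairs, n)

    R <- random_rotation()
    X <- X %*% t(R)
    X <- sweep(X, 2, colMeans(X))
    dimnames(X) <- NULL
    X
  })
}

# Bond-count distances between all atoms; disconnected components are set
# just beyond the largest in-component distance so MDS places them apart.
topo_distances <- function(graph) {
  n <- nrow(graph$atoms)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a[k]; b <- graph$bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (dist[w] > dist[v] + 1) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    D[s, ] <- dist
  }
  if (any(is.infinite(D))) {
    sep <- max(D[is.finite(D)]) + 3
    D[is.infinite(D)] <- sep
  }
  D
}

bond_length_target <- function(el_a, el_b, order) {
  shrink <- c(1.0, 0.87, 0.78)[order]
  (element_row(el_a)$covalent + element_row(el_b)$covalent) * shrink
}

# Pair list for the refinement: (i, j, target, weight, one_sided).
build_pair_terms <- function(graph, topo) {
  atoms <- graph$atoms
  bonds <- graph$bonds
  n <- nrow(atoms)
  pi <- integer(0); pj <- integer(0)
  tg <- numeric(0); wt <- numeric(0); os <- logical(0)

  cov <- vapply(atoms$element, function(e) element_row(e)$covalent, numeric(1))
  vdw <- vapply(atoms$element, function(e) element_row(e)$vdw, numeric(1))

  blen <- numeric(nrow(bonds))
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      blen[k] <- bond_length_target(atoms$element[bonds$a[k]],
                                    atoms$element[bonds$b[k]], bonds$order[k])
      pi <- c(pi, bonds$a[k]); pj <- c(pj, bonds$b[k])
      tg <- c(tg, blen[k]); wt <- c(wt, 100); os <- c(os, FALSE)
    }
  }

  # Ideal angle at each center from its coordination and bond orders.
  nb <- lapply(seq_len(n), function(i) integer(0))
  nb_bond <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    nb[[a]] <- c(nb[[a]], b); nb_bond[[a]] <- c(nb_bond[[a]], k)
    nb[[b]] <- c(nb[[b]], a); nb_bond[[b]] <- c(nb_bond[[b]], k)
  }
  for (c_at in seq_len(n)) {
    deg <- length(nb[[c_at]])
    if (deg < 2) next
    orders <- bonds$order[nb_bond[[c_at]]]
    theta <- if (any(orders == 3) || sum(orders == 2) >= 2) pi_const() else
      if (deg == 3 || any(orders == 2)) 2 * pi_const() / 3 else
      acos(-1 / 3) # tetrahedral 109.47 deg
    combs <- utils::combn(deg, 2)
    for (cc in seq_len(ncol(combs))) {
      u <- combs[1, cc]; v <- combs[2, cc]
      r1 <- blen[nb_bond[[c_at]][u]]; r2 <- blen[nb_bond[[c_at]][v]]
      t13 <- sqrt(r1^2 + r2^2 - 2 * r1 * r2 * cos(theta))
      pi <- c(pi, nb[[c_at]][u]); pj <- c(pj, nb[[c_at]][v])
      tg <- c(tg, t13); wt <- c(wt, 30); os <- c(os, FALSE)
    }
  }

  # One-sided repulsion for pairs three or more bonds apart.
  far <- which(topo >= 3 & upper.tri(topo), arr.ind = TRUE)
  if (nrow(far) > 0) {
    i <- far[, 1]; j <- far[, 2]
    pi <- c(pi, i); pj <- c(pj, j)
    tg <- c(tg, 0.70 * (vdw[i] + vdw[j]))
    wt <- c(wt, rep(20, length(i))); os <- c(os, rep(TRUE, length(i)))
  }

  list(i = pi, j = pj, target = tg, weight = wt, one_sided = os)
}

pi_const <- function() 3.14159265358979323846

refine_coords <- function(X, pairs, n) {
  if (length(pairs$i) == 0) return(X)
  i <- pairs$i; j <- pairs$j; tg <- pairs$target; wt <- pairs$weight
  os <- pairs$one_sided
  grp <- c(i, j, seq_len(n))
  energy <- function(par) {
    P <- matrix(par, n, 3)
    diff <- P[i, , drop = FALSE] - P[j, , drop = FALSE]
    d <- sqrt(rowSums(diff^2)) + 1e-12
    viol <- d - tg
    viol[os & viol > 0] <- 0
    sum(wt * viol^2)
  }
  gradient <- function(par) {
    P <- matrix(par, n, 3)
    diff <- P[i, , drop = FALSE] - P[j, , drop = FALSE]
    d <- sqrt(rowSums(diff^2)) + 1e-12
    viol <- d - tg
    viol[os & viol > 0] <- 0
    coef <- 2 * wt * viol / d
    contrib <- diff * coef
    G <- rowsum(rbind(contrib, -contrib, matrix(0, n, 3)), grp)
    as.vector(G)
  }
  fit <- stats::optim(as.vector(X), energy, gradient, method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 1e4))
  matrix(fit$par, n, 3)
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_dec <- qr(M)
  Q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Check a conformer against the geometric sanity invariants
#'
#' Bonded atom pairs must be 0.7-2.2 Angstrom apart, non-bonded pairs more
#' than 0.5 Angstrom apart, and all coordinates finite.
#'
#' @param graph The `molecule_graph` the coordinates belong to.
#' @param coords An n x 3 coordinate matrix (or a `conformer`).
#' @return `TRUE` or `FALSE`.
#' @export
conformer_valid <- function(graph, coords) {
  if (inherits(coords, "conformer")) coords <- coords$coords
  n <- nrow(graph$atoms)
  if (!is.matrix(coords) || nrow(coords) != n || !all(is.finite(coords))) {
    return(FALSE)
  }
  if (nrow(graph$bonds) > 0) {
    d <- sqrt(rowSums((coords[graph$bonds$a, , drop = FALSE] -
                       coords[graph$bonds$b, , drop = FALSE])^2))
    if (any(d < 0.7 | d > 2.2)) return(FALSE)
  }
  if (n > 1) {
    bonded <- matrix(FALSE, n, n)
    if (nrow(graph$bonds) > 0) {
      bonded[cbind(graph$bonds$a, graph$bonds$b)] <- TRUE
      bonded[cbind(graph$bonds$b, graph$bonds$a)] <- TRUE
    }
    dm <- as.matrix(stats::dist(coords))
    close <- dm <= 0.5 & upper.tri(dm) & !bonded
    if (any(close)) return(FALSE)
  }
  TRUE
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> %d atoms, seed %d\n", nrow(x$coords), x$seed))
  invisible(x)
}
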