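# Shared fixture builders. Everything is generated in code; no binary data.

# CHM made of Gaussian bumps on a flat background.
# bumps: data.frame(x, y, height, width)
bump_chm <- function(bumps, extent = 3, cell = 0.1) {
  cx <- seq(cell / 2, extent - cell / 2, by = cell)
  z <- matrix(0, length(cx), length(cx))
  for (b in seq_len(nrow(bumps))) {
    g <- outer(cx, cx, function(y, x)
      bumps$height[b] * exp(-((x - bumps$x[b])^2 + (y - bumps$y[b])^2) /
                              bumps$width[b]))
    z <- pmax(z, g)
  }
  raster_grid(z, 0, 0, cell)
}

# independent greedy descending-flood watershed oracle (naive O(n^2) scans)
oracle_watershed <- function(chm, params) {
  z <- chm$values
  nr <- nrow(z); nc <- ncol(z)
  seeds <- detect_seeds(chm, params)
  lab <- matrix(0L, nr, nc)
  for (s in seq_len(nrow(seeds))) lab[seeds$row[s], seeds$col[s]] <- s
  nbrs <- function(r, c) {
    out <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
        out <- rbind(out, c(rr, cc))
    }
    out
  }
  repeat {
    # frontier: unlabeled pixels >= min_height adjacent to a labeled pixel
    best <- NULL
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (lab[r, c] != 0L || !(z[r, c] >= params$min_height)) next
      nb <- nbrs(r, c)
      if (!any(lab[nb] != 0L)) next
      if (is.null(best) || z[r, c] > best$z) best <- list(r = r, c = c, z = z[r, c])
    }
    if (is.null(best)) break
    nb <- nbrs(best$r, best$c)
    labeled <- nb[lab[nb] != 0L, , drop = FALSE]
    hz <- z[labeled]
    pick <- labeled[order(-hz, labeled[, 1], labeled[, 2])[1], , drop = FALSE]
    lab[best$r, best$c] <- lab[pick]
  }
  # independent tolerance merge: weakest qualifying object first
  repeat {
    labs <- sort(setdiff(unique(as.vector(lab)), 0L))
    if (length(labs) < 2L) break
    top <- sapply(labs, function(l) max(z[lab == l]))
    contact_max <- rep(-Inf, length(labs))
    neighbors <- vector("list", length(labs))
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (lab[r, c] == 0L) next
      a <- lab[r, c]
      nb <- nbrs(r, c)
      others <- setdiff(unique(lab[nb]), c(0L, a))
      if (!length(others)) next
      i <- match(a, labs)
      contact_max[i] <- max(contact_max[i], z[r, c])
      neighbors[[i]] <- union(neighbors[[i]], others)
    }
    drop <- top - contact_max
    cand <- which(drop < params$tolerance & is.finite(contact_max))
    if (!length(cand)) break
    i <- cand[which.min(top[cand])]
    nbs <- neighbors[[i]]
    target <- nbs[which.max(top[match(nbs, labs)])]
    lab[lab == labs[i]] <- target
  }
  canopycce:::relabel_rowmajor(z, lab)
}

# brute-force CCE center rule: strict diagonal dominance, lower index on ties
oracle_centers <- function(S_k) {
  n <- nrow(S_k)
  out <- integer(0)
  for (i in seq_len(n)) {
    ok <- TRUE
    for (j in seq_len(n)) {
      if (j == i) next
      if (S_k[i, i] < S_k[i, j]) { ok <- FALSE; break }
      if (S_k[i, i] == S_k[i, j] && j < i) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, i)
  }
  out
}

# brute-force assignment: maximize rcon over centers, lowest center on ties
oracle_assign <- function(S_k, centers) {
  n <- nrow(S_k)
  out <- integer(n)
  for (j in seq_len(n)) {
    best <- -Inf; who <- NA_integer_
    for (c in centers) {
      r <- S_k[c, j] / S_k[c, c]
      if (r > best) { best <- r; who <- c }
    }
    out[j] <- who
  }
  out[centers] <- centers
  out
}

# random symmetric similarity-like matrix with unit diagonal
random_similarity <- function(n) {
  p <- matrix(runif(2 * n, 0, 10), ncol = 2)
  d <- as.matrix(dist(p))
  exp(-d^2 / 25)
}

# small synthetic crown segment: two separated blobs of super-points
two_blob_superpoints <- function(n_per = 30, sep = 6, seed = 3) {
  withr::with_seed(seed, {
    mk <- function(cx) data.frame(x = rnorm(n_per, cx, 0.5),
                                  y = rnorm(n_per, 0, 0.5),
                                  z = rnorm(n_per, 10, 1))
    cent <- rbind(mk(0), mk(sep))
    list(centers = cent, weights = rep(1L, 2 * n_per),
         member_map = seq_len(2 * n_per))
  })
}
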