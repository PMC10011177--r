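# Layer V: feature integration.
#
# Four methods fuse the per-feature conspicuity maps into one saliency
# map: (1) per-pixel maximum over 6 orientation-grouped maps; (2) weighted
# sum with scalar weights |Max - mean(other local maxima)|; (3) weighted
# sum with weight matrices |Max - LocalMax| built from the nearest local
# maximum at each pixel; (4) the sum of methods 2 and 3 (the default).

#' Strict local maxima of a matrix
#'
#' A pixel is a local maximum if its value is at least every value in its
#' `neighborhood x neighborhood` window and strictly exceeds at least one
#' of them; out-of-image neighbors are ignored. A plateau of equal-valued
#' adjacent maxima is collapsed to its first pixel in row-major order. A
#' constant matrix has no maxima.
#'
#' @param m Numeric matrix.
#' @param neighborhood Odd window size (default 3).
#' @param min_prominence Fraction of the global value range; maxima whose
#'   value lies below `min + min_prominence * range` are dropped (default
#'   0, keep all).
#' @return List with `locations` (k x 2 matrix of row, col; row-major
#'   order) and `values`.
#' @export
find_local_maxima <- function(m, neighborhood = 3, min_prominence = 0) {
  assert_matrix(m, "input to find_local_maxima")
  if (neighborhood %% 2 != 1 || neighborhood < 3)
    stop_config("neighborhood must be an odd integer >= 3")
  H <- nrow(m); W <- ncol(m)
  rng <- range(m)
  empty <- list(locations = matrix(0L, 0, 2,
                                   dimnames = list(NULL, c("row", "col"))),
                values = numeric(0))
  if (rng[1] == rng[2]) return(empty)
  r <- (neighborhood - 1L) %/% 2L
  pad <- matrix(-Inf, H + 2L * r, W + 2L * r)
  pad[r + seq_len(H), r + seq_len(W)] <- m
  nbr_max <- matrix(-Inf, H, W)
  for (du in -r:r) for (dv in -r:r) {
    if (du == 0 && dv == 0) next
    nbr_max <- pmax(nbr_max, pad[r + du + seq_len(H), r + dv + seq_len(W)])
  }
  cand <- which(m >= nbr_max)       # -Inf border neighbors never dominate
  cand <- cand[m[cand] > rng[1]]    # strictly above something in the image
  if (!length(cand)) return(empty)
  rows <- ((cand - 1L) %% H) + 1L
  cols <- ((cand - 1L) %/% H) + 1L
  keep <- collapse_plateaus(rows, cols, m[cand])
  rows <- rows[keep]; cols <- cols[keep]
  ord <- order(rows, cols)          # row-major
  rows <- rows[ord]; cols <- cols[ord]
  vals <- m[cbind(rows, cols)]
  if (min_prominence > 0) {
    thr <- rng[1] + min_prominence * (rng[2] - rng[1])
    sel <- vals >= thr
    rows <- rows[sel]; cols <- cols[sel]; vals <- vals[sel]
  }
  list(locations = cbind(row = rows, col = cols), values = vals)
}

# Among candidate maxima, drop all but the first row-major member of each
# 8-connected component of equal value. Returns a logical keep vector.
collapse_plateaus <- function(rows, cols, vals) {
  k <- length(rows)
  if (k <= 1) return(rep(TRUE, k))
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  by_val <- split(seq_len(k), vals)
  for (grp in by_val) {
    if (length(grp) < 2) next
    for (a in seq_along(grp)) for (b in seq_len(a - 1L)) {
      i <- grp[a]; j <- grp[b]
      if (abs(rows[i] - rows[j]) <= 1 && abs(cols[i] - cols[j]) <= 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(k), find, 0L)
  ord <- order(rows, cols)
  keep <- rep(FALSE, k)
  seen <- integer(0)
  for (i in ord) {
    if (!(roots[i] %in% seen)) { keep[i] <- TRUE; seen <- c(seen, roots[i]) }
  }
  keep
}

# Value of the nearest local maximum at every pixel (exact Euclidean
# distance transform with label propagation, compiled; deterministic
# tie resolution).
nearest_max_matrix <- function(locations, values, dims) {
  nearest_seed_values(as.integer(locations[, 1]), as.integer(locations[, 2]),
                      as.numeric(values), as.integer(dims[1]),
                      as.integer(dims[2]))
}

new_saliency_map <- function(values, method, extra = list()) {
  structure(list(values = values,
                 provenance = c(list(integration_method = method), extra)),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<saliency_map> %d x %d, method %s%s\n",
              nrow(x$values), ncol(x$values), p$integration_method,
              if (!is.null(p$n_maps)) sprintf(", scheme %d", p$n_maps) else ""))
  invisible(x)
}

# Group the 8 orientation conspicuity maps of each base channel into one
# rescaled map; intensity and opponency maps pass through.
group_conspicuity <- function(cmaps) {
  nm <- names(cmaps)
  groups <- list()
  for (base in c("I", "RG", "BY")) {
    if (base %in% nm) groups[[base]] <- cmaps[[base]]
    osel <- grep(sprintf("^O\\d+\\.%s$", base), nm, value = TRUE)
    if (length(osel))
      groups[[paste0("O.", base)]] <- normalize01(Reduce(`+`, cmaps[osel]))
  }
  groups
}

check_cmaps <- function(cmaps) {
  if (!is.list(cmaps) || length(cmaps) < 1)
    stop_input("need at least one conspicuity map")
  d <- dim(cmaps[[1]])
  for (m in cmaps) {
    assert_matrix(m, "conspicuity map")
    if (!identical(dim(m), d)) stop_input("conspicuity map shapes differ")
  }
  invisible(NULL)
}

#' Feature integration method 1: per-pixel maximum
#'
#' Orientation conspicuity maps are summed per base channel and rescaled
#' to `[0, 1]`; the saliency value at each pixel is the maximum over the
#' grouped maps (at most 6: I, RG, BY, O.I, O.RG, O.BY). The result is
#' rescaled to `[0, 1]`.
#'
#' @param cmaps Named list of conspicuity matrices as produced by
#'   [feature_conspicuity()].
#' @return A `saliency_map`.
#' @export
integrate_max <- function(cmaps) {
  check_cmaps(cmaps)
  groups <- group_conspicuity(cmaps)
  new_saliency_map(normalize01(Reduce(pmax, groups)), 1L)
}

# Shared per-map statistics for methods 2 and 3: normalized map, its
# global maximum and its local maxima.
map_stats <- function(cmaps) {
  lapply(cmaps, function(m) {
    n <- normalize01(m)
    lm <- find_local_maxima(n)
    list(map = n, max = max(n), maxima = lm)
  })
}

#' Feature integration method 2: globally weighted sum
#'
#' Each conspicuity map is rescaled to `[0, 1]` and weighted by
#' `|Max - mean|`, where `Max` is its global maximum and `mean` the
#' average of its remaining local maxima (0 if the map has no secondary
#' maxima, so a lone peak gets full weight). Maps with many equally tall
#' peaks are near-uniformly salient and get weight near zero. If every
#' weight is zero the unweighted mean is returned with a warning.
#'
#' @inheritParams integrate_max
#' @return A `saliency_map`.
#' @export
integrate_weighted_global <- function(cmaps) {
  check_cmaps(cmaps)
  st <- map_stats(cmaps)
  w <- vapply(st, function(s) {
    vals <- s$maxima$values
    other <- if (length(vals)) vals[-which.max(vals)] else numeric(0)
    m_other <- if (length(other)) mean(other) else 0
    abs(s$max - m_other)
  }, 0)
  acc <- matrix(0, nrow(cmaps[[1]]), ncol(cmaps[[1]]))
  if (sum(w) == 0) {
    warning("all feature weights are zero; falling back to unweighted mean")
    for (s in st) acc <- acc + s$map
    acc <- acc / length(st)
  } else {
    for (i in seq_along(st)) acc <- acc + w[i] * st[[i]]$map
    acc <- acc / sum(w)
  }
  new_saliency_map(normalize01(acc), 2L, list(weights = unname(w)))
}

#' Feature integration method 3: locally weighted sum
#'
#' Each map's weight is a matrix `|Max - LocalMax|`, where `LocalMax`
#' assigns to every pixel the value of its nearest local maximum. Regions
#' governed by a secondary (weaker) maximum thus contribute with weight
#' equal to that maximum's shortfall from the global peak. The weighted
#' maps are summed and divided element-wise by the summed weights (pixels
#' with zero total weight map to 0). If no map has any local maximum, or
#' all weight matrices vanish, the method falls back to
#' [integrate_weighted_global()] with a warning.
#'
#' @inheritParams integrate_max
#' @param fallback Fall back to method 2 when all weights vanish
#'   (default TRUE); otherwise return the all-zero map.
#' @return A `saliency_map`.
#' @export
integrate_weighted_local <- function(cmaps, fallback = TRUE) {
  check_cmaps(cmaps)
  st <- map_stats(cmaps)
  dims <- dim(cmaps[[1]])
  Ws <- lapply(st, function(s) {
    if (nrow(s$maxima$locations) == 0) return(matrix(0, dims[1], dims[2]))
    lmx <- nearest_max_matrix(s$maxima$locations, s$maxima$values, dims)
    abs(s$max - lmx)
  })
  if (all(vapply(Ws, function(W) all(W == 0), TRUE))) {
    if (fallback) {
      warning("all local weight matrices are zero; falling back to method 2")
      out <- integrate_weighted_global(cmaps)
      out$provenance$integration_method <- 3L
      out$provenance$fallback <- "weighted_global"
      return(out)
    }
    return(new_saliency_map(matrix(0, dims[1], dims[2]), 3L))
  }
  num <- matrix(0, dims[1], dims[2]); den <- num
  for (i in seq_along(st)) {
    num <- num + Ws[[i]] * st[[i]]$map
    den <- den + Ws[[i]]
  }
  out <- matrix(0, dims[1], dims[2])
  nz <- den > 0
  out[nz] <- num[nz] / den[nz]
  new_saliency_map(normalize01(out), 3L)
}

#' Feature integration method 4: sum of methods 2 and 3
#'
#' The default integration: the globally weighted map (method 2) and the
#' locally weighted map (method 3) are added and rescaled to `[0, 1]`,
#' combining the complementary strengths of global and local weighting.
#'
#' @inheritParams integrate_weighted_local
#' @return A `saliency_map`.
#' @export
integrate_combined <- function(cmaps, fallback = TRUE) {
  m2 <- integrate_weighted_global(cmaps)
  m3 <- integrate_weighted_local(cmaps, fallback = fallback)
  new_saliency_map(normalize01(m2$values + m3$values), 4L)
}

#' Integrate conspicuity maps by a numbered method
#'
#' @inheritParams integrate_max
#' @param method Integration method 1-4 (default 4).
#' @return A `saliency_map`.
#' @export
integrate_features <- function(cmaps, method = 4L) {
  if (!method %in% 1:4) stop_config("integration method must be 1, 2, 3 or 4")
  switch(method,
         integrate_max(cmaps),
         integrate_weighted_global(cmaps),
         integrate_weighted_local(cmaps),
         integrate_combined(cmaps))
}
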