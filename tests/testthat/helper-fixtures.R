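# shared fixtures: everything is generated in code at test time

# a coarse scene for unit tests (full-protocol geometry, coarser raster)
test_scene <- function(pixel_spacing = 0.4, image_size = c(480L, 512L),
                       caudal_angle = 10) {
  build_scene(caudal_angle = caudal_angle, pixel_spacing = pixel_spacing,
              image_size = image_size)
}

.fixture_cache <- new.env()

cached_phantom <- function(refinement = 1, conforming = FALSE) {
  key <- paste0(if (conforming) "conf" else "asym", refinement)
  if (is.null(.fixture_cache[[key]])) {
    spec <- if (conforming) {
      phantom_spec(condyle_radii = c(40, 40), intercondylar_spacing = 82,
                   refinement = refinement,
                   femur_refinement = refinement + 1)
    } else {
      phantom_spec(refinement = refinement)
    }
    .fixture_cache[[key]] <- generate_knee_phantom(spec)
  }
  .fixture_cache[[key]]
}

# independent brute-force nearest-neighbour-within-radius oracle
brute_nearest_within <- function(query, ref, radius) {
  idx <- integer(nrow(query))
  for (i in seq_len(nrow(query))) {
    d2 <- (ref[, 1] - query[i, 1])^2 + (ref[, 2] - query[i, 2])^2 +
      (ref[, 3] - query[i, 3])^2
    j <- which(d2 <= radius^2)
    idx[i] <- if (length(j)) j[which.min(d2[j])] else 0L
  }
  idx
}

# number of 8-connected foreground components of a binary matrix
count_components <- function(img) {
  img <- img != 0
  lab <- matrix(0L, nrow(img), ncol(img))
  comp <- 0L
  for (start in which(img)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    nr <- nrow(img)
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      r <- (p - 1) %% nr + 1
      cl <- (p - 1) %/% nr + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= ncol(img)) {
          q <- (cc - 1) * nr + rr
          if (img[q] && lab[q] == 0L) {
            lab[q] <- comp
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  comp
}

# unit tetrahedron: three right faces plus the sqrt(3)/2 oblique face
unit_tetrahedron <- function() {
  triangle_surface(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)),
    label = "tetra")
}

# independent oracle: ICC(2,1) from stats::aov mean squares
aov_icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   target = factor(rep(seq_len(n), k)),
                   col = factor(rep(seq_len(k), each = n)))
  a <- stats::anova(stats::aov(y ~ target + col, df))
  MSR <- a["target", "Mean Sq"]
  MSC <- a["col", "Mean Sq"]
  MSE <- a["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}
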