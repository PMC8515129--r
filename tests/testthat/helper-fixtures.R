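# Small programmatic fixtures shared across test files.

# solid cube of tumor with optional carotid columns, 1 mm isotropic
cube_mask <- function(n = 10, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxel_mask(array(1L, dim = rep(n, 3)), spacing = spacing,
             origin = origin)
}

# digitized sphere of tumor, centered at `center`, mm units
sphere_mask <- function(radius, voxel = 0.5, center = c(0, 0, 0),
                        margin = 2) {
  half <- ceiling((radius + margin) / voxel)
  xs <- (-half:half) * voxel            # grid centered at the origin
  lab <- array(0L, dim = rep(length(xs), 3))
  for (k in seq_along(xs)) {
    z <- xs[k]
    inside <- outer((xs - center[1])^2, (xs - center[2])^2, "+") +
      (z - center[3])^2 <= radius^2
    lab[, , k] <- ifelse(inside, 1L, 0L)
  }
  voxel_mask(lab, spacing = rep(voxel, 3),
             origin = c(xs[1], xs[1], xs[1]))
}

# brute-force all-pairs maximum in-plane distance (independent of the
# convex-hull implementation under test)
brute_force_feret <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(0)
  best <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    if (d > best) best <- d
  }
  best
}

# brute-force concordant-pair AUC with half-credit ties (oracle)
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# minimal valid cohort table of size n (no recurrence mechanism)
tiny_cohort <- function(n = 12, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("T%02d", 1:n),
    sex = rep(c("M", "F"), length.out = n),
    age = round(runif(n, 20, 70)),
    knosp = sample(0:4, n, replace = TRUE),
    hardy = sample(1:5, n, replace = TRUE),
    v1 = round(runif(n, 0, 5000), 2),
    v2 = round(runif(n, 500, 8000), 2),
    d1 = round(runif(n, 10, 40), 2),
    d2 = round(runif(n, 20, 32), 2),
    ki67 = sample(0:3, n, replace = TRUE),
    prl = round(runif(n, 5, 50), 2),
    testosterone = round(runif(n, 0.1, 3), 2),
    lh = round(runif(n, 0.5, 6), 2),
    fsh = round(runif(n, 1, 10), 2),
    recurrent = rep(c(0, 1), length.out = n),
    time_months = round(runif(n, 3, 84), 1),
    stringsAsFactors = FALSE)
}
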