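# Fixture builders and independent oracle implementations. Oracles are
# deliberately naive (explicit loops, textbook formulas) and share no
# code with the package internals they check.

tiny_definition <- function() {
  atlas_definition(data.frame(
    label = 1:4,
    name_area = c("area1", "area2", "area1", "area2"),
    name_largescale_region = "FRO",
    hemisphere = c("L", "L", "R", "R")))
}

# definition with every L area mirrored on the R side
random_symmetric_definition <- function(n_regions, areas_per_region, seed) {
  set.seed(seed)
  regions <- paste0("R", sample(100:999, n_regions))
  rows <- list()
  lab <- 0L
  for (hemi in c("L", "R")) {
    for (g in regions) {
      for (a in seq_len(areas_per_region)) {
        lab <- lab + 1L
        rows[[lab]] <- data.frame(label = lab,
                                  name_area = paste0(g, "_", a),
                                  name_largescale_region = g,
                                  hemisphere = hemi)
      }
    }
  }
  atlas_definition(do.call(rbind, rows))
}

# per-voxel loop over the raw arrays, one label at a time
oracle_region_stat <- function(map_arr, atlas_arr, labels, statistic) {
  fun <- switch(statistic, mean = mean, min = min, max = max, sd = sd,
                median = median)
  vapply(labels, function(lb) {
    acc <- c()
    for (k in seq_len(dim(map_arr)[3]))
      for (j in seq_len(dim(map_arr)[2]))
        for (i in seq_len(dim(map_arr)[1]))
          if (atlas_arr[i, j, k] == lb) acc <- c(acc, map_arr[i, j, k])
    if (!length(acc)) NA_real_ else fun(acc)
  }, numeric(1))
}

# dense eigendecomposition of the shifted-correlation similarity matrix
oracle_ecm_dense <- function(X) {        # X: voxels x time
  A <- (stats::cor(t(X)) + 1) / 2
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, 1]
  v <- v * sign(sum(v))
  abs(v) / sqrt(sum(v^2))
}

# textbook Kendall's W with mid-ranks and tie correction, from scratch
oracle_kendall_w <- function(series_matrix) {  # rows = series, cols = time
  K <- nrow(series_matrix)
  T <- ncol(series_matrix)
  R <- t(apply(series_matrix, 1, rank))
  if (K == 1L) R <- matrix(R, nrow = 1L)
  Rt <- colSums(R)
  S <- sum((Rt - K * (T + 1) / 2)^2)
  C <- sum(apply(series_matrix, 1, function(x) {
    g <- as.vector(table(x))
    sum(g^3 - g)
  }))
  denom <- K^2 * (T^3 - T) - K * C
  if (denom <= 0) return(0)
  12 * S / denom
}

# regional homogeneity by explicit neighbourhood gathering
oracle_reho <- function(arr4d, mask, neighborhood) {
  sp <- dim(arr4d)[1:3]
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- rowSums(abs(offs))
  offs <- offs[switch(as.character(neighborhood),
                      "7" = ord <= 1, "19" = ord <= 2, "27" = rep(TRUE, 27)), ]
  W <- array(0, dim = sp)
  for (i in seq_len(sp[1])) for (j in seq_len(sp[2])) for (k in seq_len(sp[3])) {
    if (!mask[i, j, k]) next
    series <- list()
    for (o in seq_len(nrow(offs))) {
      ii <- i + offs$dx[o]; jj <- j + offs$dy[o]; kk <- k + offs$dz[o]
      if (ii >= 1 && ii <= sp[1] && jj >= 1 && jj <= sp[2] &&
          kk >= 1 && kk <= sp[3] && mask[ii, jj, kk]) {
        series[[length(series) + 1L]] <- arr4d[ii, jj, kk, ]
      }
    }
    W[i, j, k] <- oracle_kendall_w(do.call(rbind, series))
  }
  W
}

# naive affinity propagation: per-element loops, no vectorization.
# The documented deterministic tie-break jitter is part of the
# algorithm's contract (symmetric similarities otherwise oscillate into
# the degenerate all-singleton fixed point), so the oracle applies the
# same formula before iterating.
oracle_ap <- function(S, damping, iterations) {
  N <- nrow(S)
  for (i in 1:N) for (j in 1:N) {
    S[i, j] <- S[i, j] +
      abs(S[i, j]) * .Machine$double.eps * (((i * 173 + j * 331) %% 997) / 997 - 0.5)
  }
  R <- matrix(0, N, N); A <- matrix(0, N, N)
  for (it in seq_len(iterations)) {
    Rnew <- matrix(0, N, N)
    for (i in 1:N) for (k in 1:N) {
      others <- setdiff(1:N, k)
      Rnew[i, k] <- S[i, k] - max(A[i, others] + S[i, others])
    }
    R <- damping * R + (1 - damping) * Rnew
    Anew <- matrix(0, N, N)
    for (i in 1:N) for (k in 1:N) {
      if (i == k) {
        Anew[k, k] <- sum(pmax(0, R[setdiff(1:N, k), k]))
      } else {
        Anew[i, k] <- min(0, R[k, k] + sum(pmax(0, R[setdiff(1:N, c(i, k)), k])))
      }
    }
    A <- damping * A + (1 - damping) * Anew
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (!length(ex)) ex <- which.max(diag(R) + diag(A))
  assign_ex <- integer(N)
  for (i in 1:N) assign_ex[i] <- ex[which.max(S[i, ex])]
  assign_ex[ex] <- ex
  for (e in unique(assign_ex)) {
    members <- which(assign_ex == e)
    if (length(members) > 1L) {
      best <- members[which.max(colSums(S[members, members, drop = FALSE]))]
      assign_ex[members] <- best
    }
  }
  assign_ex
}

# closed-form one-sample t (textbook formula, element by element)
oracle_ttest <- function(d) {
  d <- d[!is.na(d)]
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(mean = m, t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# in-memory region matrix straight from a numeric matrix
rm_from_matrix <- function(X, statistic = "mean") {
  M <- nrow(X); N <- ncol(X)
  def <- suppressWarnings(atlas_definition(data.frame(
    label = seq_len(M),
    name_area = paste0("a", seq_len(M)),
    name_largescale_region = "G1",
    hemisphere = rep(c("L", "R"), length.out = M))))
  atlas_arr <- array(0L, dim = c(M, 1, 1)); atlas_arr[, 1, 1] <- seq_len(M)
  atlas <- label_volume(atlas_arr)
  recs <- lapply(seq_len(N), function(j) {
    list(subject_id = sprintf("s%02d", j),
         map = scalar_volume(array(X[, j], dim = c(M, 1, 1))),
         atlas = atlas)
  })
  build_region_matrix(recs, def, statistic)
}

# adjusted Rand-style exact agreement: TRUE iff partitions identical up
# to label renaming
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

planted_two_groups <- function(seed, n_per_group = 8L, M = 12L,
                               separation = 20, noise = 0.05) {
  set.seed(seed)
  mu1 <- rnorm(M); mu2 <- mu1 + separation
  X <- cbind(matrix(mu1, M, n_per_group) + rnorm(M * n_per_group, sd = noise),
             matrix(mu2, M, n_per_group) + rnorm(M * n_per_group, sd = noise))
  truth <- rep(1:2, each = n_per_group)
  ord <- sample(2 * n_per_group)          # interleave groups
  list(S = rm_from_matrix(X[, ord]), truth = truth[ord])
}

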