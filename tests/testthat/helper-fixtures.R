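# Shared fixtures and independent oracles; everything is generated in code.

# all permutations of 1..n (for brute-force assignment/matching oracles)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- all_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    q <- p
    q[q >= i] <- q[q >= i] + 1L
    out <- rbind(out, cbind(rep(i, nrow(q)), q))
  }
  out
}

# greedy Ward agglomeration straight from the definition: at each step merge
# the pair minimising n1*n2/(n1+n2)*||c1-c2||^2, tracked with explicit
# cluster membership (O(N^3)). Independent of the package's hclust-backed
# path.
brute_ward_costs <- function(x) {
  members <- lapply(seq_len(nrow(x)), identity)
  costs <- numeric(0)
  while (length(members) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(members) - 1L)) {
      for (j in (i + 1L):length(members)) {
        ci <- colMeans(x[members[[i]], , drop = FALSE])
        cj <- colMeans(x[members[[j]], , drop = FALSE])
        ni <- length(members[[i]]); nj <- length(members[[j]])
        cost <- ni * nj / (ni + nj) * sum((ci - cj)^2)
        if (cost < best[1]) best <- c(cost, i, j)
      }
    }
    costs <- c(costs, best[1])
    members[[best[2]]] <- c(members[[best[2]]], members[[best[3]]])
    members[[best[3]]] <- NULL
  }
  costs
}

# straight-line constant-orientation trajectory
straight_trajectory <- function(n = 10, v = c(0.5, 0, 0), yaw = 0,
                                pitch = 0, roll = 0, dt = 1) {
  t <- seq(0, by = dt, length.out = n)
  pos <- outer(t / 1000, v)   # v in m/s, t in ms
  trajectory6d(t, pos, cbind(rep(yaw, n), pitch, roll))
}

# small z-normalised blob feature matrix for clustering tests
blob_features <- function(seed = 1, n_per = 60, centers = rbind(c(0, 0),
                          c(10, 10), c(0, 10)), sd = 0.3) {
  set.seed(seed)
  k <- nrow(centers)
  vals <- do.call(rbind, lapply(seq_len(k), function(j)
    sweep(matrix(rnorm(2 * n_per, sd = sd), n_per, 2), 2, centers[j, ], "+")))
  feature_matrix(vals, names = c("f1", "f2"))
}

# rotate a whole trajectory rigidly in the world frame
rotate_world <- function(traj, R0) {
  pos <- t(R0 %*% t(traj$pos))
  ori <- t(apply(traj$ori, 1, function(a) {
    ethoproto:::matrix_to_euler(R0 %*% ethoproto:::euler_to_matrix(a[1], a[2], a[3]))
  }))
  trajectory6d(traj$t, pos, ori)
}

# minimal hand-made validation_report for select_k tests
fake_report <- function(ks, instability, quality) {
  results <- stats::setNames(lapply(seq_along(ks), function(i)
    list(between = list(instability = instability[i]),
         mean_quality = quality[i])), as.character(ks))
  structure(list(k_range = as.integer(ks), conditions = "full",
                 settings = list(), results = results,
                 selected_k = NA_integer_),
            class = "validation_report")
}
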