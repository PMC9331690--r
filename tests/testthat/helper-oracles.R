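# Independent brute-force oracles for texture matrices, features,
# Shapley values and the paired-AUC bootstrap. Everything here is naive
# loops over definitions, deliberately sharing no code with the package
# internals.

ORACLE_DIRS <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
  c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

inb <- function(p, d) all(p >= 1) && all(p <= d)

# symmetric co-occurrence counts per direction, then normalized and
# averaged over directions with at least one pair
oracle_glcm <- function(lev) {
  d <- dim(lev); ng <- max(lev)
  acc <- matrix(0, ng, ng); used <- 0
  vox <- which(lev > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(ORACLE_DIRS))) {
    P <- matrix(0, ng, ng)
    for (r in seq_len(nrow(vox))) {
      p <- vox[r, ]; q <- p + ORACLE_DIRS[k, ]
      if (!inb(q, d)) next
      j <- lev[q[1], q[2], q[3]]
      if (j == 0) next
      i <- lev[p[1], p[2], p[3]]
      P[i, j] <- P[i, j] + 1
      P[j, i] <- P[j, i] + 1
    }
    if (sum(P) > 0) { acc <- acc + P / sum(P); used <- used + 1 }
  }
  if (used == 0) { acc <- matrix(0, ng, ng); acc[1, 1] <- 1; return(acc) }
  acc / used
}

oracle_glrlm <- function(lev) {
  d <- dim(lev); ng <- max(lev); lmax <- max(d)
  acc <- matrix(0, ng, lmax)
  vox <- which(lev > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(ORACLE_DIRS))) {
    dir <- ORACLE_DIRS[k, ]
    for (r in seq_len(nrow(vox))) {
      p <- vox[r, ]; i <- lev[p[1], p[2], p[3]]
      prev <- p - dir
      if (inb(prev, d) && lev[prev[1], prev[2], prev[3]] == i) next
      len <- 1; q <- p + dir
      while (inb(q, d) && lev[q[1], q[2], q[3]] == i) {
        len <- len + 1; q <- q + dir
      }
      acc[i, len] <- acc[i, len] + 1
    }
  }
  acc / nrow(ORACLE_DIRS)
}

# flood-fill zones of equal level, 26-connectivity
oracle_glszm <- function(lev) {
  d <- dim(lev); ng <- max(lev)
  seen <- array(FALSE, d)
  zones <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  vox <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    p <- vox[r, ]
    if (seen[p[1], p[2], p[3]]) next
    val <- lev[p[1], p[2], p[3]]
    queue <- list(p); seen[p[1], p[2], p[3]] <- TRUE; size <- 0
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (o in seq_len(nrow(offs))) {
        nb <- q + offs[o, ]
        if (!inb(nb, d) || seen[nb[1], nb[2], nb[3]]) next
        if (lev[nb[1], nb[2], nb[3]] == val) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue <- c(queue, list(nb))
        }
      }
    }
    zones[[length(zones) + 1]] <- c(val, size)
  }
  zm <- do.call(rbind, zones)
  P <- matrix(0, ng, max(zm[, 2]))
  for (r in seq_len(nrow(zm))) P[zm[r, 1], zm[r, 2]] <- P[zm[r, 1], zm[r, 2]] + 1
  P
}

oracle_gldm <- function(lev) {
  d <- dim(lev); ng <- max(lev)
  P <- matrix(0, ng, 27)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  vox <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    p <- vox[r, ]; i <- lev[p[1], p[2], p[3]]
    dep <- 0
    for (o in seq_len(nrow(offs))) {
      nb <- p + offs[o, ]
      if (inb(nb, d) && lev[nb[1], nb[2], nb[3]] == i) dep <- dep + 1
    }
    P[i, dep + 1] <- P[i, dep + 1] + 1
  }
  P
}

# naive double-loop evaluation of the shared size/run matrix features
oracle_srm_features <- function(P, np) {
  nr <- sum(P); ni <- nrow(P); nj <- ncol(P)
  pn <- P / nr
  out <- list(sre = 0, lre = 0, gln = 0, glnn = 0, glv = 0, hgle = 0,
              lgle = 0, rln = 0, rlnn = 0, rp = nr / np, rv = 0, rent = 0,
              srhgle = 0, srlgle = 0, lrhgle = 0, lrlgle = 0)
  mu_i <- 0; mu_j <- 0
  for (i in 1:ni) for (j in 1:nj) {
    mu_i <- mu_i + i * pn[i, j]; mu_j <- mu_j + j * pn[i, j]
  }
  for (i in 1:ni) for (j in 1:nj) {
    p <- P[i, j]
    out$sre <- out$sre + p / j^2 / nr
    out$lre <- out$lre + p * j^2 / nr
    out$hgle <- out$hgle + p * i^2 / nr
    out$lgle <- out$lgle + p / i^2 / nr
    out$srhgle <- out$srhgle + p * i^2 / j^2 / nr
    out$srlgle <- out$srlgle + p / (i^2 * j^2) / nr
    out$lrhgle <- out$lrhgle + p * i^2 * j^2 / nr
    out$lrlgle <- out$lrlgle + p * j^2 / i^2 / nr
    out$glv <- out$glv + pn[i, j] * (i - mu_i)^2
    out$rv <- out$rv + pn[i, j] * (j - mu_j)^2
    if (pn[i, j] > 0) out$rent <- out$rent - pn[i, j] * log2(pn[i, j])
  }
  for (i in 1:ni) out$gln <- out$gln + sum(P[i, ])^2 / nr
  for (j in 1:nj) out$rln <- out$rln + sum(P[, j])^2 / nr
  out$glnn <- out$gln / nr
  out$rlnn <- out$rln / nr
  out
}

oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  px <- rowSums(p)
  mu <- sum((1:ng) * px)
  sig2 <- sum(((1:ng) - mu)^2 * px)
  out <- c(Autocorrelation = 0, ClusterProminence = 0, ClusterShade = 0,
           ClusterTendency = 0, Contrast = 0, Id = 0, Idm = 0, Idmn = 0,
           Idn = 0, InverseVariance = 0, JointEnergy = 0, JointEntropy = 0)
  pd <- numeric(ng); ps <- numeric(2 * ng)
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    out["Autocorrelation"] <- out["Autocorrelation"] + i * j * v
    out["ClusterProminence"] <- out["ClusterProminence"] + (i + j - 2 * mu)^4 * v
    out["ClusterShade"] <- out["ClusterShade"] + (i + j - 2 * mu)^3 * v
    out["ClusterTendency"] <- out["ClusterTendency"] + (i + j - 2 * mu)^2 * v
    out["Contrast"] <- out["Contrast"] + (i - j)^2 * v
    out["Id"] <- out["Id"] + v / (1 + abs(i - j))
    out["Idm"] <- out["Idm"] + v / (1 + (i - j)^2)
    out["Idmn"] <- out["Idmn"] + v / (1 + ((i - j) / ng)^2)
    out["Idn"] <- out["Idn"] + v / (1 + abs(i - j) / ng)
    if (i != j) out["InverseVariance"] <- out["InverseVariance"] + v / (i - j)^2
    out["JointEnergy"] <- out["JointEnergy"] + v^2
    if (v > 0) out["JointEntropy"] <- out["JointEntropy"] - v * log2(v)
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + v
    ps[i + j] <- ps[i + j] + v
  }
  da <- sum((0:(ng - 1)) * pd)
  c(out,
    Correlation = if (sig2 > 0) (out[["Autocorrelation"]] - mu^2) / sig2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    DifferenceVariance = sum(((0:(ng - 1)) - da)^2 * pd),
    JointAverage = mu,
    MaximumProbability = max(p),
    SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    SumSquares = sig2)
}

# random blocky lesion in a small array: a few gray levels with spatial
# correlation so zones and runs are nontrivial
random_lesion <- function(seed, maxdim = 6, nlev = 4) {
  set.seed(seed)
  d <- sample(2:maxdim, 3, replace = TRUE)
  vals <- array(sample(nlev, prod(d), replace = TRUE,
                       prob = nlev:1), d)
  mask <- array(runif(prod(d)) < 0.8, d)
  if (!any(mask)) mask[1] <- TRUE
  lev <- array(0L, d)
  lev[mask] <- vals[mask]
  # re-index to consecutive levels starting at 1
  u <- sort(unique(lev[lev > 0]))
  lev[lev > 0] <- match(lev[lev > 0], u)
  lev
}

# exact Shapley values by subset enumeration
exact_shapley <- function(model_fn, x, background) {
  m <- length(x)
  v <- function(S) {
    rows <- background
    if (length(S)) rows[, S] <- matrix(x[S], nrow(rows), length(S), byrow = TRUE)
    mean(model_fn(rows))
  }
  phi <- numeric(m)
  subsets <- lapply(0:(2^m - 1), function(b) which(intToBits(b)[1:m] == 1))
  vals <- vapply(subsets, v, 0)
  names(vals) <- vapply(subsets, paste, "", collapse = ",")
  for (i in 1:m) {
    for (si in seq_along(subsets)) {
      S <- subsets[[si]]
      if (i %in% S) next
      w <- factorial(length(S)) * factorial(m - length(S) - 1) / factorial(m)
      key_with <- paste(sort(c(S, i)), collapse = ",")
      phi[i] <- phi[i] + w * (vals[[key_with]] - vals[[si]])
    }
  }
  phi
}

# paired bootstrap test of the AUC difference
bootstrap_delong_p <- function(sa, sb, y, reps = 2000, seed = 1) {
  auc1 <- function(s, y) {
    r <- rank(s)
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  set.seed(seed)
  n <- length(y)
  d <- replicate(reps, {
    idx <- sample.int(n, replace = TRUE)
    while (length(unique(y[idx])) < 2) idx <- sample.int(n, replace = TRUE)
    auc1(sa[idx], y[idx]) - auc1(sb[idx], y[idx])
  })
  min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
}
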