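# Brute-force oracles: direct double-loop evaluations of the defining sums
# of each descriptor/statistic, independent of the package implementation.

AA20 <- amino_acids()

rand_seq <- function(len) paste(sample(AA20, len, replace = TRUE),
                                collapse = "")

oracle_aac <- function(s) {
  letters <- strsplit(s, "")[[1]]
  out <- numeric(20)
  names(out) <- AA20
  for (a in AA20) {
    cnt <- 0
    for (l in letters) if (l == a) cnt <- cnt + 1
    out[a] <- cnt / length(letters)
  }
  out
}

oracle_dpc <- function(s) {
  letters <- strsplit(s, "")[[1]]
  L <- length(letters)
  dips <- as.vector(t(outer(AA20, AA20, paste0)))
  out <- numeric(400)
  names(out) <- dips
  for (i in 1:(L - 1)) {
    d <- paste0(letters[i], letters[i + 1])
    out[d] <- out[d] + 1
  }
  out / (L - 1)
}

oracle_autocorr <- function(s, p, maxlag, kind) {
  letters <- strsplit(s, "")[[1]]
  L <- length(letters)
  pv <- p[letters]
  pbar <- mean(pv)
  out <- numeric(maxlag)
  for (d in 1:maxlag) {
    acc <- 0
    for (i in 1:(L - d)) {
      acc <- acc + switch(kind,
        moreau_broto = pv[i] * pv[i + d],
        moran = (pv[i] - pbar) * (pv[i + d] - pbar),
        geary = (pv[i] - pv[i + d])^2)
    }
    out[d] <- switch(kind,
      moreau_broto = acc / (L - d),
      moran = {
        denom <- mean((pv - pbar)^2)
        if (denom == 0) 0 else (acc / (L - d)) / denom
      },
      geary = {
        denom <- sum((pv - pbar)^2) / (L - 1)
        if (denom == 0) 0 else (acc / (2 * (L - d))) / denom
      })
  }
  out
}

oracle_ctd <- function(s, groups) {
  letters <- strsplit(s, "")[[1]]
  L <- length(letters)
  out <- numeric(0)
  for (an in names(groups)) {
    gdef <- groups[[an]]
    gidx <- integer(L)
    for (i in 1:L) for (k in 1:3)
      if (letters[i] %in% gdef[[k]]) gidx[i] <- k
    comp <- sapply(1:3, function(k) sum(gidx == k) / L)
    tpairs <- list(c(1, 2), c(1, 3), c(2, 3))
    trans <- sapply(tpairs, function(pr) {
      cnt <- 0
      for (i in 1:(L - 1))
        if ((gidx[i] == pr[1] && gidx[i + 1] == pr[2]) ||
            (gidx[i] == pr[2] && gidx[i + 1] == pr[1])) cnt <- cnt + 1
      cnt / (L - 1)
    })
    dist <- numeric(0)
    for (k in 1:3) {
      pos <- which(gidx == k)
      if (length(pos) == 0) dist <- c(dist, rep(0, 5)) else {
        n <- length(pos)
        sel <- c(pos[1],
                 pos[max(1, ceiling(0.25 * n))],
                 pos[max(1, ceiling(0.50 * n))],
                 pos[max(1, ceiling(0.75 * n))],
                 pos[n])
        dist <- c(dist, 100 * sel / L)
      }
    }
    out <- c(out, comp, trans, dist)
  }
  out
}

oracle_soc <- function(s, dm, maxlag) {
  letters <- strsplit(s, "")[[1]]
  L <- length(letters)
  out <- numeric(maxlag)
  for (d in 1:maxlag) {
    acc <- 0
    for (i in 1:(L - d)) acc <- acc + dm[letters[i], letters[i + d]]^2
    out[d] <- acc
  }
  out
}

oracle_qso <- function(s, dm, maxlag, w) {
  tau <- oracle_soc(s, dm, maxlag)
  letters <- strsplit(s, "")[[1]]
  f <- sapply(AA20, function(a) sum(letters == a)) / length(letters)
  denom <- 1 + w * sum(tau)
  c(f / denom, w * tau / denom)
}

oracle_apaac <- function(s, lam, w) {
  sc <- aa_scales(c("hydropathy", "hydrophilicity"))
  letters <- strsplit(s, "")[[1]]
  L <- length(letters)
  h1 <- sc$hydropathy[letters]
  h2 <- sc$hydrophilicity[letters]
  tau <- numeric(2 * lam)
  for (k in 1:lam) {
    a1 <- 0
    a2 <- 0
    for (i in 1:(L - k)) {
      a1 <- a1 + h1[i] * h1[i + k]
      a2 <- a2 + h2[i] * h2[i + k]
    }
    tau[2 * k - 1] <- a1 / (L - k)
    tau[2 * k] <- a2 / (L - k)
  }
  f <- sapply(AA20, function(a) sum(letters == a)) / L
  denom <- 1 + w * sum(tau)
  c(f / denom, w * tau / denom)
}

oracle_apaac_tau <- function(s, lam) {
  sc <- aa_scales(c("hydropathy", "hydrophilicity"))
  letters <- strsplit(s, "")[[1]]
  L <- length(letters)
  h1 <- sc$hydropathy[letters]
  h2 <- sc$hydrophilicity[letters]
  tau <- numeric(2 * lam)
  for (k in 1:lam) {
    tau[2 * k - 1] <- sum(h1[1:(L - k)] * h1[(1 + k):L]) / (L - k)
    tau[2 * k] <- sum(h2[1:(L - k)] * h2[(1 + k):L]) / (L - k)
  }
  tau
}

# Mann-Whitney AUC with the midrank tie convention, by explicit pair loop
oracle_auc <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == -1]
  u <- 0
  for (p in pos) for (q in neg)
    u <- u + (p > q) + 0.5 * (p == q)
  100 * u / (length(pos) * length(neg))
}

# centralization and heterogeneity from a degree sequence
oracle_topology <- function(k) {
  n <- length(k)
  m <- sum(k) / 2
  dens <- 2 * m / (n * (n - 1))
  list(centralization = (n / (n - 2)) * (max(k) / (n - 1) - dens),
       heterogeneity = sqrt(mean((k - mean(k))^2)) / mean(k))
}

# small Gaussian-descriptor catalog with explicit positives
toy_catalog <- function(nd = 3, nt = 3, dims = c(5, 7), positives = NULL,
                        seed = 42) {
  set.seed(seed)
  drugs <- matrix(rnorm(nd * dims[1]), nd,
                  dimnames = list(paste0("d", 1:nd),
                                  paste0("x", 1:dims[1])))
  targets <- matrix(rnorm(nt * dims[2]), nt,
                    dimnames = list(paste0("t", 1:nt),
                                    paste0("y", 1:dims[2])))
  if (is.null(positives))
    positives <- data.frame(drug_id = c("d1", "d1", "d2", "d3"),
                            target_id = c("t1", "t2", "t2", "t3"))
  interaction_catalog(drugs, targets, positives)
}

# linearly separable labelled pair dataset (first feature decides the class)
separable_dataset <- function(n = 20, p = 6, seed = 7) {
  set.seed(seed)
  y <- rep(c(1L, -1L), length.out = n)
  x <- matrix(rnorm(n * p, sd = 0.2), n, p)
  x[, 1] <- x[, 1] + ifelse(y == 1, 3, -3)
  colnames(x) <- paste0("f", 1:p)
  pair_dataset(x, y, paste0("d", seq_len(n)), paste0("t", seq_len(n)))
}
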