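# Independent brute-force oracles: deliberately naive re-derivations of the
# descriptor formulas and the tree learner, written as plain loops straight
# from the definitions so they share no code with the package's vectorized
# paths.

AA20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

HYDROPHOBICITY <- c(
  A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, E = -0.74,
  Q = -0.85, G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50,
  M = 0.64, F = 1.19, P = 0.12, S = -0.18, T = -0.05, W = 0.81,
  Y = 0.26, V = 1.08)
HYDROPHILICITY <- c(
  A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, E = 3.0, Q = 0.2,
  G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5,
  P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)
SIDECHAIN_MASS <- c(
  A = 15, R = 101, N = 58, D = 59, C = 47, E = 73, Q = 72, G = 1,
  H = 82, I = 57, L = 57, K = 73, M = 75, F = 91, P = 42, S = 31,
  T = 45, W = 130, Y = 107, V = 43)

std_scale <- function(p) {
  p <- p[AA20]
  m <- sum(p) / 20
  (p - m) / sqrt(sum((p - m)^2) / 20)
}

random_sequence <- function(L) paste(sample(AA20, L, TRUE), collapse = "")

oracle_theta <- function(a, b) {
  s <- 0
  for (scale in list(std_scale(HYDROPHOBICITY), std_scale(HYDROPHILICITY),
                     std_scale(SIDECHAIN_MASS))) {
    s <- s + (scale[[a]] - scale[[b]])^2
  }
  s / 3
}

oracle_pseaac <- function(sequence, lambda = 10, w = 0.05) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  theta <- numeric(lambda)
  for (d in seq_len(lambda)) {
    acc <- 0
    for (i in seq_len(L - d)) acc <- acc + oracle_theta(chars[i], chars[i + d])
    theta[d] <- acc / (L - d)
  }
  f <- numeric(20)
  for (i in seq_len(L)) {
    k <- which(AA20 == chars[i])
    f[k] <- f[k] + 1 / L
  }
  den <- sum(f) + w * sum(theta)
  c(f, w * theta) / den
}

oracle_apseaac <- function(sequence, lambda = 10, w = 0.5) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  h1 <- std_scale(HYDROPHOBICITY)
  h2 <- std_scale(HYDROPHILICITY)
  tau <- numeric(2 * lambda)
  for (d in seq_len(lambda)) {
    a1 <- a2 <- 0
    for (i in seq_len(L - d)) {
      a1 <- a1 + (h1[[chars[i]]] - h1[[chars[i + d]]])^2
      a2 <- a2 + (h2[[chars[i]]] - h2[[chars[i + d]]])^2
    }
    tau[2 * d - 1] <- a1 / (L - d)
    tau[2 * d] <- a2 / (L - d)
  }
  f <- numeric(20)
  for (i in seq_len(L)) {
    k <- which(AA20 == chars[i])
    f[k] <- f[k] + 1 / L
  }
  den <- sum(f) + w * sum(tau)
  c(f, w * tau) / den
}

ORACLE_CTD_GROUPS <- list(
  list(g1 = "RKEDQN", g2 = "GASTPHY", g3 = "CLVIMFW"),
  list(g1 = "GASCTPD", g2 = "NVEQIL", g3 = "MHKFRYW"),
  list(g1 = "LIFWCMVY", g2 = "PATGS", g3 = "HQRKNED"),
  list(g1 = "GASDT", g2 = "CPNVEQIL", g3 = "KMHFRYW"),
  list(g1 = "KR", g2 = "ANCQGHILMFPSTWYV", g3 = "DE"),
  list(g1 = "EALMQKRH", g2 = "VIYCWFT", g3 = "GNPSD"),
  list(g1 = "ALFCGIVW", g2 = "RKQEND", g3 = "MSPTHY"))

oracle_ctd <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  comp <- tran <- dist <- numeric(0)
  for (attr in ORACLE_CTD_GROUPS) {
    groups <- lapply(attr, function(s) strsplit(s, "")[[1]])
    g <- vapply(chars, function(ch) {
      for (k in 1:3) if (ch %in% groups[[k]]) return(k)
      stop("unassigned residue")
    }, integer(1))
    for (k in 1:3) comp <- c(comp, sum(g == k) / L)
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      cnt <- 0
      for (i in seq_len(L - 1)) {
        if ((g[i] == pair[1] && g[i + 1] == pair[2]) ||
            (g[i] == pair[2] && g[i + 1] == pair[1])) cnt <- cnt + 1
      }
      tran <- c(tran, cnt / (L - 1))
    }
    for (k in 1:3) {
      pos <- which(g == k)
      if (length(pos) == 0) {
        dist <- c(dist, rep(0, 5))
      } else {
        n_k <- length(pos)
        idx <- c(1, ceiling(0.25 * n_k), ceiling(0.5 * n_k),
                 ceiling(0.75 * n_k), n_k)
        dist <- c(dist, pos[idx] / L)
      }
    }
  }
  unname(c(comp, tran, dist))
}

oracle_socn <- function(sequence, nlag = 20) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  tau <- numeric(nlag)
  for (d in seq_len(nlag)) {
    for (i in seq_len(L - d)) {
      tau[d] <- tau[d] + oracle_theta(chars[i], chars[i + d])
    }
  }
  tau
}

oracle_qso <- function(sequence, nlag = 20, w = 0.1) {
  chars <- strsplit(sequence, "")[[1]]
  f <- numeric(20)
  for (ch in chars) f[which(AA20 == ch)] <- f[which(AA20 == ch)] + 1
  tau <- oracle_socn(sequence, nlag)
  den <- sum(f) + w * sum(tau)
  c(f / den, w * tau / den)
}

oracle_pssm_bigram <- function(scores) {
  L <- nrow(scores)
  p <- matrix(0, L, 20)
  for (i in seq_len(L)) for (j in 1:20) p[i, j] <- 1 / (1 + exp(-scores[i, j]))
  out <- numeric(400)
  for (m in 1:20) {
    for (n in 1:20) {
      acc <- 0
      for (t in seq_len(L - 1)) acc <- acc + p[t, m] * p[t + 1, n]
      out[20 * (m - 1) + n] <- acc / (L - 1)
    }
  }
  out
}

# --- exhaustive ADTree learner -------------------------------------------
# Same algorithm re-derived with naive loops: every candidate precondition
# (TRUE plus each prediction-node path, in creation order), every threshold
# (midpoints of consecutive sorted unique masked values per feature), Z
# computed by direct summation, ties broken by earlier feature, smaller
# threshold, fewer precondition conjuncts.

oracle_z <- function(w, y, pmask, cmask) {
  wpp <- sum(w[pmask & cmask & y > 0])
  wpn <- sum(w[pmask & cmask & y < 0])
  wnp <- sum(w[pmask & !cmask & y > 0])
  wnn <- sum(w[pmask & !cmask & y < 0])
  2 * (sqrt(wpp * wpn) + sqrt(wnp * wnn)) + sum(w[!pmask])
}

oracle_adtree <- function(x, y01, B, epsilon = 1) {
  y <- ifelse(y01 == 1, 1, -1)
  n <- nrow(x)
  w <- rep(1 / n, n)
  root <- 0.5 * log((sum(w[y > 0]) + epsilon) / (sum(w[y < 0]) + epsilon))
  w <- w * exp(-y * root)
  preconds <- list(list(mask = rep(TRUE, n), nconj = 0))
  rules <- list()
  for (round in seq_len(B)) {
    best <- NULL
    for (pi in seq_along(preconds)) {
      m <- preconds[[pi]]$mask
      for (j in seq_len(ncol(x))) {
        vals <- sort(unique(x[m, j]))
        if (length(vals) < 2) next
        for (k in seq_len(length(vals) - 1)) {
          t <- (vals[k] + vals[k + 1]) / 2
          z <- oracle_z(w, y, m, x[, j] < t)
          cand <- list(z = z, j = j, t = t,
                       nconj = preconds[[pi]]$nconj, pi = pi)
          replace <- FALSE
          if (is.null(best)) {
            replace <- TRUE
          } else if (z < best$z - 1e-12) {
            replace <- TRUE
          } else if (z <= best$z + 1e-12) {
            if (cand$j != best$j) replace <- cand$j < best$j
            else if (cand$t != best$t) replace <- cand$t < best$t
            else replace <- cand$nconj < best$nconj
          }
          if (replace) best <- cand
        }
      }
    }
    if (is.null(best)) break
    m <- preconds[[best$pi]]$mask
    cmask <- x[, best$j] < best$t
    a <- 0.5 * log((sum(w[m & cmask & y > 0]) + epsilon) /
                     (sum(w[m & cmask & y < 0]) + epsilon))
    b <- 0.5 * log((sum(w[m & !cmask & y > 0]) + epsilon) /
                     (sum(w[m & !cmask & y < 0]) + epsilon))
    for (i in seq_len(n)) {
      if (m[i] && cmask[i]) w[i] <- w[i] * exp(-y[i] * a)
      else if (m[i]) w[i] <- w[i] * exp(-y[i] * b)
    }
    rules[[round]] <- list(feature = colnames(x)[best$j], threshold = best$t,
                           score_true = a, score_false = b, z = best$z,
                           precond = best$pi)
    preconds <- c(preconds,
                  list(list(mask = m & cmask, nconj = preconds[[best$pi]]$nconj + 1),
                       list(mask = m & !cmask, nconj = preconds[[best$pi]]$nconj + 1)))
  }
  # margins by nested-if evaluation over the stored precondition masks is
  # awkward; recompute per instance from the rule list instead
  margin <- function(xrow) {
    masks <- list(rep(TRUE, 1))
    out <- root
    state <- list(list(holds = TRUE, nconj = 0))
    for (r in rules) {
      holds <- state[[r$precond]]$holds
      c_holds <- xrow[[r$feature]] < r$threshold
      if (holds) out <- out + if (c_holds) r$score_true else r$score_false
      state <- c(state, list(list(holds = holds && c_holds),
                             list(holds = holds && !c_holds)))
    }
    out
  }
  list(root = root, rules = rules, margin = margin)
}
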