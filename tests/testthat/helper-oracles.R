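## Independent brute-force reference implementations used to cross-check the
## package.  Deliberately naive (explicit loops, no shared code with R/).

## Mode of a length-weighted value histogram by exhaustive counting over bins
## centred on multiples of `binWidth`; returns the centre of the local-max
## bin nearest `P` (ties: higher mass, then smaller centre).
oracleHistogramPeak <- function(values, weights, binWidth, P) {
  idx <- as.integer(round(values / binWidth))
  grid <- seq(min(idx) - 1L, max(idx) + 1L)
  mass <- numeric(length(grid))
  for (i in seq_along(values)) {
    k <- which(grid == idx[i])
    mass[k] <- mass[k] + weights[i]
  }
  best <- NULL
  for (k in seq(2L, length(grid) - 1L)) {
    if (mass[k] > 0 && mass[k] >= mass[k - 1L] && mass[k] >= mass[k + 1L]) {
      cand <- c(center = grid[k] * binWidth, mass = mass[k])
      if (is.null(best)) best <- cand
      else {
        dNew <- abs(cand["center"] - P); dOld <- abs(best["center"] - P)
        if (dNew < dOld ||
            (dNew == dOld && cand["mass"] > best["mass"]) ||
            (dNew == dOld && cand["mass"] == best["mass"] &&
             cand["center"] < best["center"]))
          best <- cand
      }
    }
  }
  unname(best["center"])
}

oracleNormalize <- function(cn, bias, clamp = 0.5) {
  f <- min(cn / 2, 1)
  corr <- f * bias
  if (corr > clamp) corr <- clamp
  if (corr < -clamp) corr <- -clamp
  max(cn + corr, 0)
}

oracleEqualize <- function(v) v * (1 + v / 100)^(0.75 * v)

oracleLog2ToAbs <- function(values, P, weights) {
  ## lower weighted median by cumulative scan
  o <- order(values)
  v <- values[o]; w <- weights[o]
  tot <- sum(w); acc <- 0; med <- v[length(v)]
  for (i in seq_along(v)) {
    acc <- acc + w[i]
    if (acc >= tot / 2) { med <- v[i]; break }
  }
  P * 2^(values - med)
}

oracleErrorScore <- function(rd, sv, P) {
  if (is.na(rd)) rd <- 0
  if (is.na(sv)) sv <- P
  (rd - sv)^2
}

oracleMSE <- function(x, xh) { s <- 0; for (i in seq_along(x)) s <- s + (x[i] - xh[i])^2; s / length(x) }
oracleMAE <- function(x, xh) { s <- 0; for (i in seq_along(x)) s <- s + abs(x[i] - xh[i]); s / length(x) }
oracleMLRE <- function(x, xh) {
  s <- 0
  for (i in seq_along(x)) s <- s + abs(log((x[i] + 1) / (xh[i] + 1)))
  s / length(x)
}

oracleResVar <- function(x, xh) {
  z <- x - xh
  lev <- unique(round(x))
  tot <- 0
  for (l in lev) {
    zi <- z[round(x) == l]
    tot <- tot + sum((zi - mean(zi))^2) / length(zi)
  }
  tot / length(lev)
}

oracleMCC <- function(tc, pc) {
  cls <- c("deletion", "normal", "amplification")
  TP <- TN <- FP <- FN <- 0
  for (cl in cls) for (i in seq_along(tc)) {
    t <- tc[i] == cl; p <- pc[i] == cl
    if (t && p) TP <- TP + 1
    if (!t && !p) TN <- TN + 1
    if (!t && p) FP <- FP + 1
    if (t && !p) FN <- FN + 1
  }
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  if (den == 0) 0 else (TP * TN - FP * FN) / den
}

## Naive O(n^2)-style merge: repeatedly join the first mergeable neighbour
## pair (contiguous, same chromosome, equal one-decimal CN).
oracleMerge <- function(df) {
  r1 <- function(x) sign(x) * floor(abs(x) * 10 + 0.5 + 1e-9) / 10
  repeat {
    merged <- FALSE
    if (nrow(df) >= 2L) for (i in seq_len(nrow(df) - 1L)) {
      j <- i + 1L
      if (df$chrom[i] == df$chrom[j] && df$end[i] + 1L == df$start[j] &&
          r1(df$cn[i]) == r1(df$cn[j])) {
        wi <- df$end[i] - df$start[i] + 1L
        wj <- df$end[j] - df$start[j] + 1L
        df$cn[i] <- (df$cn[i] * wi + df$cn[j] * wj) / (wi + wj)
        df$e[i] <- (df$e[i] * wi + df$e[j] * wj) / (wi + wj)
        df$end[i] <- df$end[j]
        df <- df[-j, , drop = FALSE]
        merged <- TRUE
        break
      }
    }
    if (!merged) return(df)
  }
}

## Per-gene weighted CN by explicit per-segment arithmetic.
oracleGeneCN <- function(geneStart, geneEnd, segs, P) {
  L <- geneEnd - geneStart + 1
  covered <- 0; weighted <- 0
  for (i in seq_len(nrow(segs))) {
    s <- max(geneStart, segs$start[i]); e <- min(geneEnd, segs$end[i])
    if (s <= e) {
      covered <- covered + (e - s + 1)
      weighted <- weighted + segs$cn[i] * (e - s + 1)
    }
  }
  (weighted + P * (L - covered)) / L
}

## Independent scalar rule table for one bin (classes precomputed).
oracleDecide <- function(clsRd, clsSv, referee, cnRd, cnSv, P) {
  if (clsRd == "absent" && clsSv == "absent") return(P)
  if (clsSv == "absent") return(cnRd)
  if (clsRd == "absent") return(cnSv)
  if (clsRd == clsSv)
    return(if (clsRd == "amplification") cnSv else cnRd)
  if (referee == clsRd) return(cnRd)
  if (referee == clsSv) return(cnSv)
  P
}

randomTrack <- function(n, chrom = "1", role = "coverage",
                        scale = "absolute_cn", vmin = 0, vmax = 6) {
  len <- sample(50:500, n, replace = TRUE)
  gap <- sample(0:100, n, replace = TRUE)
  start <- cumsum(gap) + cumsum(c(0, len[-n])) + 1
  CallerTrack(rep(chrom, n), start, start + len - 1,
              runif(n, vmin, vmax), role, scale)
}
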