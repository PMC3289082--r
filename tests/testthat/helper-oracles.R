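# Independent brute-force oracles. These re-derive everything from first
# principles (peptide-mass algebra, direct pair loops, pairwise rank
# counting) and deliberately share no code with the package internals.

# A complementary (+1,+1) pair sums to M + 2*proton and a charge-weighted
# (+1,+2) pair to M + 3*proton, where M = z*mp - z*proton is the neutral
# peptide mass under the precursor charge hypothesis z.
bf_cp_target <- function(mp, z, n_protons_in_pair, proton = 1.00728) {
  (z * mp - z * proton) + n_protons_in_pair * proton
}

bf_pair_relations <- function(sp, tol = 0.5, losses_enabled = TRUE,
                              constants = mass_constants()) {
  n <- length(sp$mz)
  rows <- list()
  loss_set <- c(none = 0)
  if (losses_enabled) {
    loss_set <- c(none = 0, h2o = constants$h2o, nh3 = constants$nh3,
                  co = constants$co, nh = constants$nh)
  }
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        for (kind in c("CP11", "CP12_LOW2", "CP12_HIGH2")) {
          lhs <- switch(kind,
            CP11 = sp$mz[i] + sp$mz[j],
            CP12_LOW2 = 2 * sp$mz[i] + sp$mz[j],
            CP12_HIGH2 = sp$mz[i] + 2 * sp$mz[j]
          )
          np <- if (kind == "CP11") 2 else 3
          for (z in 2:3) {
            tgt <- bf_cp_target(sp$precursor_mz, z, np, constants$proton)
            for (ln in names(loss_set)) {
              if (abs(lhs + loss_set[[ln]] - tgt) <= tol) {
                rows[[length(rows) + 1]] <- data.frame(
                  i = i, j = j, kind = kind, z = z, loss = ln,
                  stringsAsFactors = FALSE
                )
                break  # first matching loss variant only
              }
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(i = integer(0), j = integer(0), kind = character(0),
                      z = integer(0), loss = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

bf_doubly_charged <- function(sp, tol = 0.5, constants = mass_constants()) {
  n <- length(sp$mz)
  flags <- logical(n)
  tgt <- bf_cp_target(sp$precursor_mz, 3, 3, constants$proton)
  for (k in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == k) next
      if (abs(sp$mz[j] - (2 * sp$mz[k] - constants$proton)) <= tol ||
          abs(2 * sp$mz[k] + sp$mz[j] - tgt) <= tol) {
        flags[k] <- TRUE
        break
      }
    }
  }
  flags
}

# recompute delta_rcp directly from a relation table
bf_delta_rcp <- function(rel, intensity) {
  cp1 <- unique(rel[rel$kind == "CP11", c("i", "j")])
  t1 <- 0
  if (nrow(cp1) > 0) {
    den <- sum(intensity[cp1$j])
    t1 <- (if (den > 0) sum(intensity[cp1$i]) / den else 0) + 0.5
  }
  cp2 <- unique(rel[rel$kind != "CP11", c("i", "j", "kind")])
  t2 <- 0
  if (nrow(cp2) > 0) {
    two <- ifelse(cp2$kind == "CP12_LOW2", cp2$i, cp2$j)
    one <- ifelse(cp2$kind == "CP12_LOW2", cp2$j, cp2$i)
    den <- sum(intensity[one])
    t2 <- if (den > 0) sum(intensity[two]) / den else 0
  }
  t1 - t2
}

bf_n_bs <- function(sp, tol = 0.5, nt = 1, constants = mass_constants()) {
  n <- length(sp$mz)
  if (n < 2) return(0)
  shifts <- c(0, constants$h2o, constants$nh3, constants$co, constants$nh,
              -constants$h2o, -constants$nh3, -constants$co, -constants$nh)
  basics <- constants$residue_masses[c("K", "R", "H")]
  count <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- abs(sp$mz[j] - sp$mz[i])
      hit <- FALSE
      for (r in basics) {
        for (s in shifts) if (abs(d + s - r) <= tol) hit <- TRUE
      }
      if (hit) count <- count + 1
    }
  }
  count / nt
}

# AUC by explicit pairwise concordance counting
bf_auc <- function(scores, labels) {
  pos <- which(labels == 3)
  neg <- which(labels == 2)
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (scores[p] > scores[q]) + 0.5 * (scores[p] == scores[q])
    }
  }
  tot / (length(pos) * length(neg))
}

random_spectrum <- function(n_peaks = 12, mp = NULL, id = "rand") {
  if (is.null(mp)) mp <- runif(1, 400, 900)
  spectrum(id, mp,
           mz = runif(n_peaks, 100, 2 * mp),
           intensity = rlnorm(n_peaks))
}

relation_key <- function(rel) {
  sort(paste(rel$i, rel$j, rel$kind, rel$z, rel$loss))
}
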