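# Independent oracles used to cross-check package implementations.
# These deliberately share no code with the package internals.

# Needleman-Wunsch global alignment (match +1, mismatch 0, linear gap -g),
# returning matched positions / shorter-sequence length.
oracle_identity <- function(a, b, gap = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -gap * (0:n)
  S[1, ] <- -gap * (0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(
        S[i, j] + (A[i] == B[j]),
        S[i, j + 1] - gap,
        S[i + 1, j] - gap
      )
    }
  }
  # traceback counting matched identical positions
  i <- n; j <- m; matches <- 0L
  while (i > 0 && j > 0) {
    if (S[i + 1, j + 1] == S[i, j] + (A[i] == B[j])) {
      matches <- matches + (A[i] == B[j])
      i <- i - 1; j <- j - 1
    } else if (S[i + 1, j + 1] == S[i, j + 1] - gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  matches / min(n, m)
}

# all-pairs greedy clustering oracle on an explicit visit order
oracle_cluster_count <- function(seqs, order_idx, threshold, gap = 1) {
  reps <- integer(0)
  for (i in order_idx) {
    joined <- FALSE
    for (r in reps) {
      if (oracle_identity(seqs[r], seqs[i], gap) > threshold) {
        joined <- TRUE
        break
      }
    }
    if (!joined) reps <- c(reps, i)
  }
  length(reps)
}

# direct per-element categorical cross-entropy summation
oracle_cross_entropy <- function(targets, predictions, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(targets))
  vals <- numeric(0)
  for (r in which(mask)) {
    s <- 0
    for (k in seq_len(ncol(targets))) {
      if (targets[r, k] > 0) s <- s - targets[r, k] * log(predictions[r, k])
    }
    vals <- c(vals, s)
  }
  mean(vals)
}

# Henderson-Hasselbalch net charge from an explicit per-group table
oracle_net_charge <- function(seq, pH, include_termini = TRUE) {
  pka_pos <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
  pka_neg <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  chars <- strsplit(seq, "")[[1]]
  total <- 0
  for (g in names(pka_pos)) {
    n <- if (g == "Nterm") as.integer(include_termini) else sum(chars == g)
    total <- total + n / (1 + 10^(pH - pka_pos[[g]]))
  }
  for (g in names(pka_neg)) {
    n <- if (g == "Cterm") as.integer(include_termini) else sum(chars == g)
    total <- total - n / (1 + 10^(pka_neg[[g]] - pH))
  }
  total
}

# Welch t statistic, Welch-Satterthwaite df, two-sided p (hand formula)
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# brute-force residue contact pairs between two chains of a trajectory frame
oracle_contacts <- function(traj, frame, chain_a, chain_b, cutoff = 4.0,
                            heavy_only = TRUE) {
  at <- traj$atoms
  keep <- function(ch) which(at$chain == ch &
                               (!heavy_only | toupper(at$element) != "H"))
  pairs <- list()
  for (i in keep(chain_a)) {
    for (j in keep(chain_b)) {
      d <- sqrt(sum((traj$coords[frame, i, ] - traj$coords[frame, j, ])^2))
      if (d <= cutoff) {
        pairs[[length(pairs) + 1L]] <- c(at$resid[i], at$resid[j])
      }
    }
  }
  if (length(pairs) == 0L) return(matrix(integer(0), ncol = 2))
  unique(do.call(rbind, pairs))
}

# two-pass mean/variance
oracle_two_pass_var <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}

# random two-chain frame generator for contact oracle checks
random_toy_traj <- function(n_atoms = 30, n_frames = 1, spread = 12) {
  atoms <- tibble::tibble(
    name = "CA",
    resname = "ALA",
    chain = rep(c("A", "B"), length.out = n_atoms),
    resid = rep(seq_len(ceiling(n_atoms / 3)), each = 3)[seq_len(n_atoms)],
    element = sample(c("C", "N", "O", "H"), n_atoms, replace = TRUE)
  )
  coords <- array(runif(n_frames * n_atoms * 3, 0, spread),
                  dim = c(n_frames, n_atoms, 3))
  structure(list(atoms = atoms, coords = coords), class = "pep_trajectory")
}

# random canonical peptide (test-local)
random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}
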