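# Shared fixtures and independent oracles, all built in code at test time.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
BASES <- c("A", "C", "G", "T")

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA, n, replace = TRUE), collapse = "")
}

SENSE_CODONS <- local({
  all3 <- apply(expand.grid(BASES, BASES, BASES), 1L, paste0, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

# deterministic fixture CDS long enough for every mutation string of the
# NF1 screen: codon 339 = AAA (so c.1015A>T creates a TAA stop) and codon
# 1371 = AAG (so c.4113G>T is the K>N missense); 2382 codons = 7146 nt.
fixture_t1_cds <- function(upstream_len = 2000L) {
  set.seed(424242)
  n_codons <- 2382L
  cods <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  cods[1L] <- "ATG"
  cods[339L] <- "AAA"
  cods[1371L] <- "AAG"
  cods[n_codons] <- "TAA"
  up <- paste(sample(BASES, upstream_len, replace = TRUE), collapse = "")
  cds_model(paste(cods, collapse = ""), upstream_seq = up, id = "t1_fixture")
}

# small CDS for quick variant round-trips
fixture_small_cds <- function(n_codons = 120L, seed = 7L) {
  set.seed(seed)
  cods <- sample(SENSE_CODONS, n_codons, replace = TRUE)
  cods[1L] <- "ATG"
  cods[n_codons] <- "TAA"
  cds_model(paste(cods, collapse = ""), id = "small")
}

# random in-CDS variant away from the start and stop codons
random_cds_variant <- function(cds) {
  n <- nchar(cds$cds_seq)
  kind <- sample(c("substitution", "deletion", "insertion", "delins",
                   "inversion"), 1L)
  start <- sample(4:(n - 12L), 1L)
  span <- sample(1:6, 1L)
  switch(kind,
    substitution = {
      rb <- substr(cds$cds_seq, start, start)
      new_v(sprintf("c.%d%s>%s", start, rb, sample(setdiff(BASES, rb), 1L)))
    },
    deletion = new_v(sprintf("c.%d_%ddel", start, start + span - 1L)),
    insertion = new_v(sprintf("c.%d_%dins%s", start, start + 1L,
      paste(sample(BASES, sample(1:5, 1L), replace = TRUE), collapse = ""))),
    delins = new_v(sprintf("c.%d_%ddelins%s", start, start + span - 1L,
      paste(sample(BASES, sample(1:5, 1L), replace = TRUE), collapse = ""))),
    inversion = new_v(sprintf("c.%d_%dinv", start,
                              start + max(2L, span) - 1L)))
}
new_v <- function(s) parse_hgvs_c(s)

# ---- oracles -------------------------------------------------------------

# brute-force truncated-window rolling median
oracle_rolling_median <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    median(x[max(1L, i - h):min(n, i + h)]), 0)
}

# independently written affine-gap DP (R, matrix form); gap cost
# open + ext * (L - 1), same convention as the package
oracle_align_score <- function(a, b, S, open, ext, local) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(-Inf, n + 1L, m + 1L); E <- H; Fm <- H
  H[1L, 1L] <- 0
  for (j in seq_len(m)) {
    v <- -(open + (j - 1) * ext)
    H[1L, j + 1L] <- if (local) 0 else v
    if (!local) E[1L, j + 1L] <- v
  }
  for (i in seq_len(n)) {
    v <- -(open + (i - 1) * ext)
    H[i + 1L, 1L] <- if (local) 0 else v
    if (!local) Fm[i + 1L, 1L] <- v
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1L, j + 1L] <- max(H[i + 1L, j] - open, E[i + 1L, j] - ext)
    Fm[i + 1L, j + 1L] <- max(H[i, j + 1L] - open, Fm[i, j + 1L] - ext)
    h <- max(H[i, j] + S[A[i], B[j]], E[i + 1L, j + 1L], Fm[i + 1L, j + 1L])
    if (local) h <- max(h, 0)
    H[i + 1L, j + 1L] <- h
    best <- max(best, h)
  }
  if (local) best else H[n + 1L, m + 1L]
}

# exhaustive DP-free enumeration of global affine alignments (tiny inputs)
enum_global_score <- function(a, b, S, open, ext) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B))
      best <- max(best, S[A[i], B[j]] + rec(i + 1L, j + 1L, "M"))
    if (i <= length(A))
      best <- max(best, -(if (last == "D") ext else open) +
                    rec(i + 1L, j, "D"))
    if (j <= length(B))
      best <- max(best, -(if (last == "I") ext else open) +
                    rec(i, j + 1L, "I"))
    best
  }
  rec(1L, 1L, "M")
}

# local score by enumerating every substring pair (tiny inputs only)
enum_local_score <- function(a, b, S, open, ext) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a))
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b))
      best <- max(best, enum_global_score(substr(a, i1, i2),
                                          substr(b, j1, j2), S, open, ext))
  best
}

# score a gapped alignment pair under the package's affine convention
score_alignment <- function(aln, scheme) {
  a <- strsplit(aln[1], "")[[1]]; b <- strsplit(aln[2], "")[[1]]
  s <- 0; last <- "M"
  for (k in seq_along(a)) {
    if (a[k] == "-") {
      s <- s - (if (last == "I") scheme$gap_extend else scheme$gap_open)
      last <- "I"
    } else if (b[k] == "-") {
      s <- s - (if (last == "D") scheme$gap_extend else scheme$gap_open)
      last <- "D"
    } else {
      s <- s + scheme$matrix[a[k], b[k]]
      last <- "M"
    }
  }
  s
}

# build a callset directly from record fields
make_records <- function(...) {
  d <- data.table::data.table(...)
  if ("pos" %in% names(d)) d$pos <- as.integer(d$pos)
  if ("depth" %in% names(d)) d$depth <- as.integer(d$depth)
  defaults <- list(chrom = "chr1", id = ".", qual = 99, depth = 20,
                   mq = 50, gt = "hom")
  for (k in names(defaults))
    if (!k %in% names(d)) d[[k]] <- rep(defaults[[k]], length.out = nrow(d))
  d
}
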