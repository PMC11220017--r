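# Independent brute-force oracles: materialize every spectral box at
# every level and test membership pixel by pixel. Deliberately naive and
# separate from the package's histogram-based path.

oracle_entropy <- function(values) {
  counts <- table(values)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# occupied level-j boxes of a single-band frame at depth S, by
# enumerating all 2^j boxes and scanning every pixel
oracle_sbm <- function(frame, S, j) {
  vals <- as.vector(frame)
  width <- 2^(S - j)
  occupied <- 0L
  for (lo in seq(0, 2^S - 1, by = width)) {
    hit <- FALSE
    for (v in vals) if (v >= lo && v < lo + width) { hit <- TRUE; break }
    if (hit) occupied <- occupied + 1L
  }
  occupied
}

oracle_level_hist <- function(frame, S, j) {
  vals <- as.vector(frame)
  width <- 2^(S - j)
  counts <- vapply(seq(0, 2^S - 1, by = width),
                   function(lo) sum(vals >= lo & vals < lo + width),
                   numeric(1))
  counts[counts > 0]
}

oracle_metrics <- function(frame, S) {
  js <- 1:(S - 1)
  sbm <- vapply(js, function(j) oracle_sbm(frame, S, j), numeric(1))
  fj <- vapply(js, function(j) {
    counts <- oracle_level_hist(frame, S, j)
    min(1, oracle_entropy(rep(seq_along(counts), counts)) / j)
  }, numeric(1))
  w <- fj * sbm
  list(sfd_esr = sum(log(sbm) / log(2^S)) / (S - 1),
       sfd_dsr = sum(log(sbm) / log(2^js)) / (S - 1),
       ew_sfd = sum(ifelse(w >= 1, log(pmax(w, 1)) / log(2^js), 0)) / (S - 1),
       entropy = oracle_entropy(as.vector(frame)))
}

# all single-band 2x2 frames at depth S (one per value code)
all_tiny_frames <- function(S) {
  lapply(0:(2^(S * 4) - 1), function(code)
    matrix((code %/% 2^(S * (0:3))) %% 2^S, 2, 2))
}

random_frame <- function(S, h = 8, w = 8) {
  matrix(sample(0:(2^S - 1), h * w, replace = TRUE), h, w)
}
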