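# Shared fixtures, all generated in code at test time.

randMatrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# two toy omic blocks over the same samples
toyBlocks <- function(n = 12, p1 = 6, p2 = 4, seed = 1, label1 = "rna",
                      label2 = "protein") {
  set.seed(seed)
  sids <- sprintf("s%02d", seq_len(n))
  b1 <- matrix(rnorm(n * p1), n, p1,
               dimnames = list(sids, paste0("g", seq_len(p1))))
  b2 <- matrix(5 * rnorm(n * p2) + 2, n, p2,
               dimnames = list(sids, paste0("pr", seq_len(p2))))
  list(OmicBlock(b1, label1), OmicBlock(b2, label2))
}

# principal angles (radians) between the column spaces of A and B
principalAngles <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(pmax(s, -1), 1))
}

writeToyBlockTSV <- function(block, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(as.matrix(block)),
                   as.matrix(block), check.names = FALSE)
  data.table::fwrite(df, path, sep = sep)
  path
}
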