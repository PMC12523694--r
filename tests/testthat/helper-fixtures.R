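# Fixtures built in code; no files on disk except through tempfile().

# random pedigree with nf founders and n total animals; parents always have
# smaller index, so generation order is guaranteed
randomPedigree <- function(n, nf = max(4, round(n / 5)), seed = 1) {
  set.seed(seed)
  an <- sprintf("p%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (nf + 1):n) {
    pr <- sample(seq_len(i - 1), 2)
    sire[i] <- an[pr[1]]
    dam[i] <- an[pr[2]]
  }
  readPedigree(data.frame(animal = an, sire = sire, dam = dam,
                          stringsAsFactors = FALSE))
}

trioPedigree <- function() {
  readPedigree(data.frame(animal = c("S", "D", "O"),
                          sire = c(NA, NA, "S"),
                          dam = c(NA, NA, "D")))
}

# dense joint-distribution H: the oracle for the hybrid inverse
denseH <- function(A, Gb, gid) {
  Af <- as.matrix(relValues(A))
  pos <- match(gid, relIndex(A))
  A11 <- Af[-pos, -pos, drop = FALSE]
  A12 <- Af[-pos, pos, drop = FALSE]
  A22 <- Af[pos, pos, drop = FALSE]
  A22i <- solve(A22)
  Gm <- as.matrix(relValues(Gb))
  H <- matrix(0, nrow(Af), nrow(Af))
  H[-pos, -pos] <- A11 + A12 %*% A22i %*% (Gm - A22) %*% A22i %*% t(A12)
  H[-pos, pos] <- A12 %*% A22i %*% Gm
  H[pos, -pos] <- t(H[-pos, pos])
  H[pos, pos] <- Gm
  dimnames(H) <- dimnames(Af)
  H
}

# tiny lactation table used by editing / design tests
toyLactations <- function() {
  data.frame(
    cow = c("c1", "c1", "c2", "c3", "c4", "c5", "c6"),
    herd = "h1",
    parity = c(1, 2, 1, 1, 1, 1, 2),
    calving_date = as.Date(c("2005-11-01", "2006-12-01", "2005-11-15",
                             "2005-12-01", "2005-11-20", "2005-11-25",
                             "2005-11-05")),
    birth_date = as.Date(c("2003-09-01", "2003-09-01", "2003-09-15",
                           "2003-10-01", "2003-09-20", "2003-09-25",
                           "2002-06-05")),
    milk_kg = c(8000, 8500, 7000, 7500, 9000, 6500, 7200),
    fat_kg = c(280, 300, 250, 260, 310, 230, 255),
    protein_kg = c(260, 280, 230, 240, 290, 215, 235),
    stringsAsFactors = FALSE)
}

toyPedForLactations <- function() {
  readPedigree(data.frame(
    animal = c("b1", "b2", paste0("c", 1:6)),
    sire = c(NA, NA, "b1", "b1", "b2", "b2", "b1", "b2"),
    dam = rep(NA, 8), stringsAsFactors = FALSE))
}
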