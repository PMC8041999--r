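# Independent oracles and small fixture builders shared across tests.

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  kirdock:::quaternion_to_rotation(q)
}

# Textbook pooled/Welch t-test from summary statistics, written separately
# from the package implementation.
oracle_t_p <- function(m1, s1, n1, m2, s2, n2, pooled = TRUE) {
  if (pooled) {
    sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    t <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- s1^2 / n1 + s2^2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  2 * pt(-abs(t), df)
}

# Two-stage step-up discoveries, built on stats::p.adjust ("BH") as an
# independent route: step-up rejection at level a <=> adjusted p <= a.
oracle_bky_discoveries <- function(p, Q) {
  m <- length(p)
  adj <- p.adjust(p, method = "BH")
  r1 <- sum(adj <= Q / (1 + Q))
  m0 <- m - r1
  if (m0 == 0) return(rep(TRUE, m))
  p.adjust(p, method = "BH") <= Q * m / m0
}

# Exposed spherical area of sphere 1 (radius r1) overlapped by sphere 2
# (radius r2) at centre distance d: full area minus the spherical cap.
oracle_two_sphere_exposed <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# Minimal ternary-complex model with one receptor residue placed at an
# engineered heavy-atom distance from one HLA residue. kir_resno controls
# footprint region assignment.
micro_model <- function(dist = 3.9, kir_resno = 44L) {
  mk <- function(chain, resno, x, y, z, elety = "CB") {
    data.frame(chain = chain, resno = resno, insert = "", resid = "ALA",
               elety = elety, elesy = "C", alt = "", o = 1,
               x = x, y = y, z = z, het = FALSE, stringsAsFactors = FALSE)
  }
  pep <- do.call(rbind, lapply(1:9, function(i)
    mk("C", i, 100 + 3.2 * i, 50, 0, "CA")))
  atoms <- rbind(
    mk("A", 80L, 0, 0, 0),                  # HLA residue
    mk("A", 10L, 60, 60, 60),               # far HLA residue
    mk("B", 1L, -50, -50, -50),             # b2m stand-in
    pep,
    mk("D", kir_resno, dist, 0, 0),         # receptor residue
    mk("D", 150L, 40, 40, 40))              # far receptor residue
  struct <- kirdock:::new_kir_structure(atoms, title = "micro")
  suppressWarnings(build_complex_model(
    struct, chains = list(hla = "A", b2m = "B", peptide = "C", kir = "D")))
}
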