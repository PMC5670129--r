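# Shared fixture builders (all generated in code; no stored data).

# Two Gaussian classes separated by `sep` sigma along a random direction.
twoGaussians <- function(n = 40, d = 10, sep = 6, seed = 1) {
  set.seed(seed)
  dir <- rnorm(d)
  dir <- dir / sqrt(sum(dir^2))
  X <- rbind(matrix(rnorm(n * d), n, d),
             sweep(matrix(rnorm(n * d), n, d), 2, sep * dir, "+"))
  list(X = X, y = rep(c("a", "b"), each = n))
}

# Fifteen six-rank bacterial-style lineages (two Gram types, nested ranks).
bacterialLineages <- function() {
  c("GramPos;Bacilli;Bacillales;Staphylococcaceae;Staphylococcus;S. aureus",
    "GramPos;Bacilli;Bacillales;Staphylococcaceae;Staphylococcus;S. epidermidis",
    "GramPos;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus;S. agalactiae",
    "GramPos;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus;S. pyogenes",
    "GramPos;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus;S. pneumoniae",
    "GramPos;Clostridia;Clostridiales;Clostridiaceae;Clostridium;C. difficile",
    "GramNeg;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Escherichia;E. coli",
    "GramNeg;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Klebsiella;K. pneumoniae",
    "GramNeg;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Klebsiella;K. oxytoca",
    "GramNeg;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Enterobacter;E. cloacae",
    "GramNeg;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Enterobacter;E. aerogenes",
    "GramNeg;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Proteus;P. mirabilis",
    "GramNeg;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Serratia;S. marcescens",
    "GramNeg;Gammaproteobacteria;Enterobacterales;Yersiniaceae;Yersinia;Y. enterocolitica",
    "GramNeg;Gammaproteobacteria;Pseudomonadales;Pseudomonadaceae;Pseudomonas;P. aeruginosa")
}

# Small hierarchy with an only-child genus: G2 holds a single leaf.
onlyChildData <- function(nPerLeaf = 15, d = 20, sep = 6, seed = 7) {
  lineages <- c("A;G1;s1", "A;G1;s2", "A;G2;s3", "B;G3;s4", "B;G3;s5")
  set.seed(seed)
  means <- matrix(0, length(lineages), d)
  topDir <- list(A = rnorm(d), B = rnorm(d))
  topDir <- lapply(topDir, function(v) v / sqrt(sum(v^2)))
  for (i in seq_along(lineages)) {
    parts <- strsplit(lineages[i], ";")[[1]]
    mu <- sep * topDir[[parts[1]]]
    for (lvl in 2:3) {
      set.seed(seed + 100 * lvl + sum(utf8ToInt(paste(parts[1:lvl],
                                                      collapse = ""))))
      v <- rnorm(d)
      mu <- mu + sep * v / sqrt(sum(v^2))
    }
    means[i, ] <- mu
  }
  set.seed(seed + 1)
  X <- do.call(rbind, lapply(seq_along(lineages), function(i) {
    sweep(matrix(rnorm(nPerLeaf * d), nPerLeaf, d), 2, means[i, ], "+")
  }))
  rownames(X) <- sprintf("s%03d", seq_len(nrow(X)))
  labels <- rep(lineages, each = nPerLeaf)
  list(X = X, labels = labels, tree = buildTree(lineages))
}
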