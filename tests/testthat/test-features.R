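tb <- ec_tables()

test_that("mole_percent sums to 100 and matches simple cases", {
  expect_equal(unname(mole_percent("AAAA")["A"]), 100)
  expect_equal(unname(mole_percent("ACAC")[c("A", "C")]), c(50, 50))
  expect_true(all(mole_percent("MKVLA")[c("M","K","V","L","A")] == 20))
  for (s in replicate(20, random_seq(sample(5:500, 1))))
    expect_equal(sum(mole_percent(s)), 100, tolerance = 1e-12)
  expect_error(mole_percent(""), "nonempty")
})

test_that("dayhoffstat is mole percent over background frequency", {
  d <- dayhoffstat("CCCC", tb)
  expect_equal(unname(d["C"]), 100 / tb$dayhoff[["C"]])
  expect_equal(unname(d["A"]), 0)
  # definitional fixed point: composition equal to the background -> 1
  counts <- round(tb$dayhoff / sum(tb$dayhoff) * 1000)
  seq_bg <- paste(rep(names(counts), counts), collapse = "")
  d_bg <- dayhoffstat(seq_bg, tb)
  expect_true(all(abs(d_bg - 1) < 0.05))
})

test_that("molecular weight and atom counts obey peptide-bond additivity", {
  expect_equal(molecular_weight("G", tb), 75.07, tolerance = 0.01)
  expect_equal(unname(atom_counts("G", tb)[c("C","H","N","O","S")]),
               c(2, 5, 1, 2, 0))
  set.seed(7)
  for (i in 1:100) {
    a <- random_seq(sample(2:80, 1)); b <- random_seq(sample(2:80, 1))
    expect_equal(molecular_weight(paste0(a, b), tb),
                 molecular_weight(a, tb) + molecular_weight(b, tb) - 18.0153,
                 tolerance = 1e-9)
    ab <- atom_counts(paste0(a, b), tb)
    sep <- atom_counts(a, tb) + atom_counts(b, tb) -
      c(C = 0, H = 2, N = 0, O = 1, S = 0, total = 3)
    expect_equal(ab, sep)
  }
  # sulfur only from C and M
  s <- "CCMMGAV"
  expect_equal(unname(atom_counts(s, tb)["S"]), 4)
})

test_that("net charge is strictly decreasing and pI is its root", {
  grid <- seq(0, 14, by = 0.5)
  set.seed(11)
  for (s in replicate(50, random_seq(sample(10:200, 1)))) {
    ch <- net_charge(s, grid, tb)
    expect_true(all(diff(ch) < 0))
  }
  for (s in replicate(10, random_seq(50))) {
    pi <- theoretical_pi(s, tb)
    expect_lt(abs(net_charge(s, pi, tb)), 1e-3)
  }
  expect_gt(theoretical_pi(strrep("K", 20), tb),
            theoretical_pi(strrep("D", 20), tb))
})

test_that("charge, gravy, aliphatic and extinction match definitions", {
  expect_equal(charge("KDKD"), 0)
  expect_equal(charge("KKK"), 3)
  expect_equal(charge("HH"), 1)
  expect_equal(gravy(strrep("I", 7), tb), tb$kd[["I"]])
  s <- random_seq(100, seed = 2)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(gravy(s, tb), gravy(perm, tb))
  expect_equal(aliphatic_index(strrep("A", 10)), 100)
  expect_equal(aliphatic_index(strrep("V", 10)), 290)
  expect_equal(aliphatic_index("GGSS"), 0)
  expect_equal(unname(extinction_coefficients("GGG")), c(0, 0))
  expect_equal(unname(extinction_coefficients("WW")), c(11000, 11000))
  expect_equal(unname(extinction_coefficients("CC")), c(0, 125))
})

test_that("instability index follows the dipeptide weight formula", {
  expect_equal(instability_index("MK", tb), 5 * tb$diwv["M", "K"])
  L <- 12
  expect_equal(instability_index(strrep("G", L), tb),
               10 * (L - 1) * tb$diwv["G", "G"] / L)
  expect_error(instability_index("A", tb), "length")
  # order matters: a witness pair with same composition, different index
  expect_false(isTRUE(all.equal(instability_index("MKVLA", tb),
                                instability_index("ALVKM", tb))))
})

test_that("property classes and charged residue counts", {
  pc <- property_class_composition("FFFF", tb)
  expect_equal(pc$mole_percent[pc$class == "aromatic"], 100)
  s <- random_seq(200, seed = 4)
  pc <- property_class_composition(s, tb)
  expect_true(all(pc$mole_percent >= 0 & pc$mole_percent <= 100))
  basic <- pc$count[pc$class == "basic"]
  acidic <- pc$count[pc$class == "acidic"]
  expect_lte(basic + acidic - pc$count[pc$class == "charged"], 0)
  expect_equal(unname(charged_residue_counts("DDEE")), c(4, 0))
  expect_equal(unname(charged_residue_counts("RKRK")), c(0, 4))
  expect_equal(unname(charged_residue_counts("GGG")), c(0, 0))
})

test_that("extract_features yields the 73-feature schema, deterministically", {
  s <- random_seq(120, seed = 9)
  v <- extract_features(s)
  expect_length(v, 73)
  expect_true(all(is.finite(v)))
  expect_identical(v, extract_features(s))
  # permutation changes only order-dependent features
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  v2 <- extract_features(perm)
  comp <- setdiff(names(v), "instability_index")
  expect_equal(v[comp], v2[comp])
})

test_that("feature tables round-trip through TSV", {
  recs <- data.frame(id = paste0("s", 1:3),
                     residues = replicate(3, random_seq(60)),
                     stringsAsFactors = FALSE)
  tab <- extract_table(recs)
  expect_equal(dim(tab), c(3, 73))
  expect_equal(rownames(tab), recs$id)
  f <- tempfile(fileext = ".tsv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_equal(back, tab[, , drop = FALSE], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(colnames(back), colnames(tab))
})

test_that("extracted features match the frozen reference oracle", {
  fix <- read.delim(test_path("fixtures", "reference_peptides.tsv"),
                    stringsAsFactors = FALSE)
  peps <- c(pep1 = "GLSDGEWQLVLNVWGKVEADIPGHGQEVLIR",
            pep2 = "KWCFRVCYRGICYRRCR")
  tb_bj <- ec_tables("bjellqvist")
  get <- function(p, q) fix$value[fix$peptide == p & fix$quantity == q]
  for (p in names(peps)) {
    s <- peps[[p]]
    expect_equal(nchar(s), get(p, "length"))
    expect_lt(abs(molecular_weight(s) - get(p, "mol_weight")), 0.01)
    expect_lt(abs(theoretical_pi(s, tb_bj) - get(p, "pI_bjellqvist")), 0.1)
    expect_equal(gravy(s), get(p, "gravy"), tolerance = 1e-3)
    expect_lt(abs(instability_index(s) - get(p, "instability_index")), 1e-2)
    ext <- extinction_coefficients(s)
    expect_equal(unname(ext["reduced"]), get(p, "ext_reduced"))
    expect_equal(unname(ext["cystine"]), get(p, "ext_cystine"))
    m <- mole_percent(s)
    for (r in c("A", "C", "G", "W"))
      expect_equal(unname(m[r]), get(p, paste0(r, "_mole")),
                   tolerance = 1e-6)
  }
})
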