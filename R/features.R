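#' @noRd
split_residues <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("sequence must be a single nonempty string", call. = FALSE)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(s), AA_ALPHABET)
  if (length(bad))
    stop("non-standard residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  s
}

residue_counts <- function(seq) {
  s <- split_residues(seq)
  setNames(tabulate(match(s, AA_ALPHABET), nbins = 20L), AA_ALPHABET)
}

#' Amino-acid composition in mole percent
#'
#' @param seq a single residue string over the 20 standard one-letter codes.
#' @return Named numeric vector over the 20 residues; values sum to 100.
#' @export
mole_percent <- function(seq) {
  n <- residue_counts(seq)
  100 * n / sum(n)
}

#' Dayhoffstat: mole percent over Dayhoff background frequency
#'
#' Each residue's molar percentage divided by its Dayhoff statistic — the
#' residue's relative occurrence per 1000 amino acids normalized to 100
#' (the EMBOSS pepstats definition). Residues absent from the sequence score 0.
#'
#' @inheritParams mole_percent
#' @param tables physicochemical tables from [ec_tables()].
#' @return Named numeric vector over the 20 residues.
#' @export
dayhoffstat <- function(seq, tables = ec_tables()) {
  mole_percent(seq) / tables$dayhoff
}

#' Molecular weight (average masses)
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @inheritParams dayhoffstat
#' @return Weight in Daltons.
#' @export
molecular_weight <- function(seq, tables = ec_tables()) {
  n <- residue_counts(seq)
  sum(n * (tables$mass - tables$water)) + tables$water
}

# ionizable group counts for a sequence; terminal groups depend on the
# first/last residue only through the Bjellqvist residue-specific pKas
ionizable_groups <- function(seq, tables) {
  n <- residue_counts(seq)
  pka <- tables$pka
  first <- substr(seq, 1, 1)
  last <- substr(seq, nchar(seq), nchar(seq))
  pick <- function(generic, specific) {
    i <- match(specific, pka$group)
    if (!is.na(i)) i else match(generic, pka$group)
  }
  rows <- c(pick("Nterm", paste0("Nterm_", first)),
            pick("Cterm", paste0("Cterm_", last)))
  counts <- c(1, 1)
  side <- pka[grepl("^[A-Z]$", pka$group), ]
  rows <- c(rows, match(side$group, pka$group))
  counts <- c(counts, n[side$group])
  data.frame(pka = pka$pka[rows], sign = pka$sign[rows], count = counts)
}

#' Net charge of a sequence at a given pH
#'
#' Henderson-Hasselbalch sum over the N- and C-terminus and the ionizable
#' side chains (K, R, H positive; D, E, C, Y negative), with group counts
#' taken from the sequence. Strictly decreasing in pH.
#'
#' @inheritParams dayhoffstat
#' @param pH pH value(s).
#' @return Net charge (vectorized over `pH`).
#' @export
net_charge <- function(seq, pH, tables = ec_tables()) {
  g <- ionizable_groups(seq, tables)
  vapply(pH, function(p) {
    pos <- g$sign == "+"
    sum(g$count[pos] / (1 + 10^(p - g$pka[pos]))) -
      sum(g$count[!pos] / (1 + 10^(g$pka[!pos] - p)))
  }, numeric(1))
}

#' Theoretical isoelectric point
#'
#' The pH in \[0, 14\] at which [net_charge()] is zero, found by bisection.
#'
#' @inheritParams dayhoffstat
#' @param tol bisection tolerance in pH units.
#' @return pH value.
#' @export
theoretical_pi <- function(seq, tables = ec_tables(), tol = 1e-4) {
  lo <- 0; hi <- 14
  # net charge is strictly decreasing: positive at 0, negative at 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(seq, mid, tables) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Summed residue charge
#'
#' Fixed per-residue charge sum (pepstats convention): K, R = +1; D, E = -1;
#' H = +0.5; all others 0.
#'
#' @inheritParams mole_percent
#' @return Numeric charge.
#' @export
charge <- function(seq) {
  n <- residue_counts(seq)
  n[["K"]] + n[["R"]] + 0.5 * n[["H"]] - n[["D"]] - n[["E"]]
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the sequence.
#'
#' @inheritParams dayhoffstat
#' @return Numeric GRAVY score.
#' @export
gravy <- function(seq, tables = ec_tables()) {
  n <- residue_counts(seq)
  sum(n * tables$kd) / sum(n)
}

#' Aliphatic index
#'
#' `X_Ala + 2.9 X_Val + 3.9 (X_Ile + X_Leu)` where `X_r` is the mole percent
#' of residue r (Ikai's relative volume of aliphatic side chains).
#'
#' @inheritParams mole_percent
#' @return Numeric index.
#' @export
aliphatic_index <- function(seq) {
  m <- mole_percent(seq)
  m[["A"]] + 2.9 * m[["V"]] + 3.9 * (m[["I"]] + m[["L"]])
}

#' Instability index
#'
#' `(10 / L) * sum DIWV(seq[i], seq[i+1])` over adjacent residue pairs, with
#' the Guruprasad et al. dipeptide instability weights.
#'
#' @inheritParams dayhoffstat
#' @return Numeric index.
#' @export
instability_index <- function(seq, tables = ec_tables()) {
  s <- split_residues(seq)
  L <- length(s)
  if (L < 2L) stop("instability index needs length >= 2", call. = FALSE)
  (10 / L) * sum(tables$diwv[cbind(s[-L], s[-1])])
}

#' Elemental composition
#'
#' Counts of C, H, N, O and S atoms: element-wise sum of the free-amino-acid
#' formulas minus one water (2 H, 1 O) per peptide bond.
#'
#' @inheritParams dayhoffstat
#' @return Named integer vector `c(C, H, N, O, S, total)`.
#' @export
atom_counts <- function(seq, tables = ec_tables()) {
  n <- residue_counts(seq)
  at <- colSums(tables$elemental * as.numeric(n))
  L <- sum(n)
  at["H"] <- at["H"] - 2 * (L - 1)
  at["O"] <- at["O"] - (L - 1)
  c(at, total = sum(at))
}

#' Molar extinction coefficients at 280 nm
#'
#' `reduced = 5500 nW + 1490 nY`; `cystine` additionally counts 125 per
#' cystine pair (`floor(nC / 2)`).
#'
#' @inheritParams mole_percent
#' @return Named vector `c(reduced, cystine)` in 1/(M cm).
#' @export
extinction_coefficients <- function(seq) {
  n <- residue_counts(seq)
  reduced <- 5500 * n[["W"]] + 1490 * n[["Y"]]
  c(reduced = reduced, cystine = reduced + 125 * (n[["C"]] %/% 2))
}

#' Residue property-class composition
#'
#' Counts and mole percentages of the nine EMBOSS pepstats property classes
#' (tiny, small, aliphatic, aromatic, non-polar, polar, charged, basic,
#' acidic).
#'
#' @inheritParams dayhoffstat
#' @return Data frame with columns `class`, `count`, `mole_percent`.
#' @export
property_class_composition <- function(seq, tables = ec_tables()) {
  n <- residue_counts(seq)
  L <- sum(n)
  counts <- vapply(tables$classes, function(res) sum(n[res]), numeric(1))
  data.frame(class = names(tables$classes), count = unname(counts),
             mole_percent = unname(100 * counts / L),
             stringsAsFactors = FALSE)
}

#' Counts of charged residues
#'
#' @inheritParams mole_percent
#' @return Named vector `c(negative, positive)`: D+E and R+K counts.
#' @export
charged_residue_counts <- function(seq) {
  n <- residue_counts(seq)
  c(negative = n[["D"]] + n[["E"]], positive = n[["R"]] + n[["K"]])
}

#' Extract the full physicochemical feature vector for one sequence
#'
#' Computes every feature named by the schema (73 under the default
#' reconstruction), each quantity computed once. Deterministic for a given
#' schema and tables version.
#'
#' @inheritParams dayhoffstat
#' @param schema from [feature_schema()].
#' @return Named numeric vector in schema order, with a `schema_version`
#'   attribute.
#' @export
extract_features <- function(seq, schema = feature_schema(),
                             tables = ec_tables()) {
  n <- residue_counts(seq)
  L <- sum(n)
  mole <- 100 * n / L
  dayh <- mole / tables$dayhoff
  cls_cnt <- vapply(tables$classes, function(res) sum(n[res]), numeric(1))

  s <- split_residues(seq)
  instab <- if (L >= 2L)
    (10 / L) * sum(tables$diwv[cbind(s[-L], s[-1])]) else NA_real_
  at <- colSums(tables$elemental * as.numeric(n))
  at["H"] <- at["H"] - 2 * (L - 1)
  at["O"] <- at["O"] - (L - 1)
  ext <- 5500 * n[["W"]] + 1490 * n[["Y"]] + 125 * (n[["C"]] %/% 2)

  vals <- c(
    setNames(mole, paste0(AA_ALPHABET, "_mole")),
    setNames(dayh, paste0(AA_ALPHABET, "_dayhoff")),
    setNames(100 * cls_cnt / L, paste0(names(tables$classes), "_mole")),
    setNames(cls_cnt, paste0(names(tables$classes), "_count")),
    length = L,
    mol_weight = sum(n * (tables$mass - tables$water)) + tables$water,
    charge = n[["K"]] + n[["R"]] + 0.5 * n[["H"]] - n[["D"]] - n[["E"]],
    pI = theoretical_pi(seq, tables),
    neg_count = n[["D"]] + n[["E"]],
    pos_count = n[["R"]] + n[["K"]],
    atoms_C = at[["C"]], atoms_H = at[["H"]], atoms_N = at[["N"]],
    atoms_O = at[["O"]], atoms_S = at[["S"]],
    gravy = sum(n * tables$kd) / L,
    aliphatic_index = mole[["A"]] + 2.9 * mole[["V"]] +
      3.9 * (mole[["I"]] + mole[["L"]]),
    instability_index = instab,
    ext_cystine = ext
  )
  missing <- setdiff(schema$feature, names(vals))
  if (length(missing))
    stop("schema names features the extractor does not provide: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- vals[schema$feature]
  if (any(!is.finite(out)))
    stop("non-finite feature value(s) for sequence of length ", L,
         call. = FALSE)
  attr(out, "schema_version") <- attr(schema, "schema_version")
  out
}

#' Extract a feature table for a set of records
#'
#' @param records data frame with `id` and `residues` columns.
#' @inheritParams extract_features
#' @return Numeric matrix, one row per record (rownames = ids), columns in
#'   schema order; `schema_version` attribute set.
#' @export
extract_table <- function(records, schema = feature_schema(),
                          tables = ec_tables()) {
  stopifnot(nrow(records) > 0)
  rows <- lapply(records$residues, extract_features, schema = schema,
                 tables = tables)
  m <- do.call(rbind, rows)
  rownames(m) <- records$id
  attr(m, "schema_version") <- attr(schema, "schema_version")
  m
}

#' Write / read a feature table as TSV
#'
#' Values are written at 10 significant digits ("." decimal separator), so the
#' round trip is lossless to well below feature noise.
#'
#' @param table matrix from [extract_table()].
#' @param path TSV path.
#' @return `path` invisibly / the matrix.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(id = rownames(table),
                   signif(as.data.frame(table), 10),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
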