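#' Physicochemical reference tables
#'
#' Loads the versioned physicochemical constants shipped with the package:
#' average residue masses (Da), Dayhoff background frequencies (relative
#' occurrence per 1000 residues normalized to 100), Kyte-Doolittle hydropathy,
#' free-amino-acid elemental compositions (C, H, N, O, S), the 400-entry
#' dipeptide instability weight table (DIWV; Guruprasad et al. 1992), pKa
#' values for the ionizable groups, and the nine EMBOSS pepstats residue
#' property classes. All tables are plain TSV files under `inst/extdata` and
#' were verified against the EMBOSS/ProtParam reference implementations.
#'
#' @param pka_set which pKa table to use for the theoretical pI:
#'   `"emboss"` (pepstats values, the default) or `"bjellqvist"` (the
#'   ProtParam set, including its residue-specific terminal adjustments).
#' @return A list with elements `mass`, `dayhoff`, `kd` (named numeric vectors
#'   over the 20 standard residues), `elemental` (20 x 5 matrix), `diwv`
#'   (20 x 20 matrix, rows = first residue), `pka` (data frame with columns
#'   `group`, `pka`, `sign`), `classes` (named list of residue sets), and
#'   `pka_set`.
#' @export
ec_tables <- function(pka_set = c("emboss", "bjellqvist")) {
  pka_set <- match.arg(pka_set)
  key <- paste0("tables_", pka_set)
  if (!is.null(.pkg_env[[key]])) return(.pkg_env[[key]])

  aa <- read.delim(ec_extdata("aa_properties.tsv"), stringsAsFactors = FALSE)
  stopifnot(identical(sort(aa$residue), AA_ALPHABET))
  rownames(aa) <- aa$residue
  aa <- aa[AA_ALPHABET, ]

  diwv_long <- read.delim(ec_extdata("diwv.tsv"), stringsAsFactors = FALSE)
  diwv <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diwv[cbind(diwv_long$first, diwv_long$second)] <- diwv_long$weight

  pka_all <- read.delim(ec_extdata("pka_sets.tsv"), stringsAsFactors = FALSE)
  pka <- pka_all[pka_all$set == pka_set, c("group", "pka", "sign")]

  cls <- read.delim(ec_extdata("property_classes.tsv"),
                    stringsAsFactors = FALSE)
  classes <- lapply(cls$residues, function(s) strsplit(s, "")[[1]])
  names(classes) <- cls$class

  elemental <- as.matrix(aa[, c("C", "H", "N", "O", "S")])

  out <- list(
    mass = setNames(aa$avg_mass, aa$residue),
    dayhoff = setNames(aa$dayhoff, aa$residue),
    kd = setNames(aa$kyte_doolittle, aa$residue),
    elemental = elemental,
    diwv = diwv,
    pka = pka,
    classes = classes,
    pka_set = pka_set,
    water = 18.0153
  )
  stopifnot(all(out$dayhoff > 0))
  .pkg_env[[key]] <- out
  out
}

#' Feature schema
#'
#' The ordered list of feature names computed by [extract_features()], with a
#' group tag recording whether the quantity comes from the pepstats-style
#' set, the ProtParam-style set, or is shared by both. The default schema
#' (`"v1"`) has exactly 73 features: 20 residue mole percentages, 20
#' dayhoffstat values, 9 property-class mole percentages and 9 counts,
#' sequence length, molecular weight, summed charge, theoretical pI,
#' negatively and positively charged residue counts, C/H/N/O/S atom counts,
#' GRAVY, aliphatic index, instability index, and the cystine extinction
#' coefficient.
#'
#' @param version schema version string; only `"v1"` ships with the package,
#'   but any TSV with `feature` and `group` columns can be supplied as a file
#'   path for drop-in alternative reconstructions.
#' @return A data frame with columns `feature` and `group`, plus a
#'   `schema_version` attribute.
#' @export
feature_schema <- function(version = "v1") {
  path <- if (file.exists(version)) version else
    ec_extdata(paste0("schema_", version, ".tsv"))
  sc <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("feature", "group") %in% names(sc)),
            !anyDuplicated(sc$feature))
  attr(sc, "schema_version") <- version
  sc
}
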