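# Chemical identity, molecular weight, unit conversion and perfluorinated
# chain length.

# 2021 IUPAC standard atomic weights (conventional values for elements with
# an interval), g/mol. Covers the elements occurring in PFAS rosters plus
# common organics.
ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998403163, Na = 22.98976928, Si = 28.085, P = 30.973761998,
  S = 32.06, Cl = 35.45, K = 39.0983, Br = 79.904, I = 126.90447
)

HALFLIFE_CLASSES <- c("lt_half_day", "lt_1_week", "lt_2_months",
                      "gt_2_months", "unknown")

#' Load a chemical roster
#'
#' Reads a roster CSV with one row per chemical. Required columns are
#' `dtxsid`, `casrn`, `name` and `abbreviation`; `formula`, `smiles`, `rb2p`
#' (blood-to-plasma concentration ratio), `rb2p_source` and `halflife_class`
#' are optional and filled with `NA` when absent. Molecular weight is
#' computed from `formula` where available.
#'
#' @param path Path to a roster CSV file.
#' @return A tibble with one row per chemical, including a computed `mw`
#'   column (g/mol, `NA` when no formula is given).
#' @examples
#' roster <- load_roster(system.file("extdata", "pfas_roster.csv",
#'                                   package = "bcbcr"))
#' nrow(roster)
#' @export
load_roster <- function(path) {
  required <- c("dtxsid", "casrn", "name", "abbreviation")
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("roster is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  optional <- c(formula = NA_character_, smiles = NA_character_,
                rb2p = NA_character_, rb2p_source = NA_character_,
                halflife_class = NA_character_)
  for (col in names(optional)) {
    if (!col %in% names(df)) df[[col]] <- optional[[col]]
  }
  dup <- df$dtxsid[duplicated(df$dtxsid)]
  if (length(dup) > 0) {
    stop("duplicate dtxsid in roster: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  df$rb2p <- as.numeric(df$rb2p)
  if (any(!is.na(df$rb2p) & df$rb2p <= 0)) {
    stop("rb2p must be > 0 when present", call. = FALSE)
  }
  df$halflife_class <- ifelse(is.na(df$halflife_class), "unknown",
                              df$halflife_class)
  bad_hl <- setdiff(unique(df$halflife_class), HALFLIFE_CLASSES)
  if (length(bad_hl) > 0) {
    stop("unknown halflife_class value(s): ", paste(bad_hl, collapse = ", "),
         call. = FALSE)
  }
  df$mw <- vapply(df$formula, function(f) {
    if (is.na(f) || !nzchar(f)) NA_real_ else molecular_weight(f)
  }, numeric(1), USE.NAMES = FALSE)
  tibble::as_tibble(df[, c("dtxsid", "casrn", "name", "abbreviation",
                           "formula", "smiles", "mw", "rb2p", "rb2p_source",
                           "halflife_class")])
}

#' Molecular weight from a molecular formula
#'
#' Sums standard (2021 IUPAC) atomic weights over a plain molecular formula
#' such as `"C8HF15O2"`. Element symbols with optional integer counts only;
#' no parentheses, isotopes or charges.
#'
#' @param formula Molecular formula string.
#' @return Molecular weight in g/mol.
#' @examples
#' molecular_weight("H2O")
#' molecular_weight("C8HF15O2")  # PFOA
#' @export
molecular_weight <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) {
    stop("cannot parse molecular formula: ", formula, call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  total <- 0
  for (tok in tokens) {
    sym <- gsub("[0-9]", "", tok)
    cnt <- gsub("[^0-9]", "", tok)
    n <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!sym %in% names(ATOMIC_WEIGHTS)) {
      stop("unknown element symbol '", sym, "' in formula ", formula,
           call. = FALSE)
    }
    total <- total + ATOMIC_WEIGHTS[[sym]] * n
  }
  total
}

#' Convert between molar and mass concentration
#'
#' A 1 uM solution of a chemical with molecular weight MW g/mol contains
#' MW ng/mL, so the conversion is a single multiplication;
#' `mass_to_molar()` is its exact inverse.
#'
#' @param conc_um Concentration in micromolar (uM); must be >= 0.
#' @param conc_ngml Concentration in ng/mL; must be >= 0.
#' @param mw Molecular weight in g/mol; must be > 0.
#' @return Concentration in ng/mL (`molar_to_mass`) or uM (`mass_to_molar`).
#' @examples
#' molar_to_mass(1, 414.07)   # 1 uM PFOA in ng/mL
#' mass_to_molar(414.07, 414.07)
#' @export
molar_to_mass <- function(conc_um, mw) {
  if (any(conc_um < 0, na.rm = TRUE)) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  if (any(mw <= 0, na.rm = TRUE)) stop("mw must be > 0", call. = FALSE)
  conc_um * mw
}

#' @rdname molar_to_mass
#' @export
mass_to_molar <- function(conc_ngml, mw) {
  if (any(conc_ngml < 0, na.rm = TRUE)) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  if (any(mw <= 0, na.rm = TRUE)) stop("mw must be > 0", call. = FALSE)
  conc_ngml / mw
}

# Heavy-atom graph of a molecule from its SMILES. Returns list(symbol=,
# bonds=data.frame(a1, a2, order)). Parsing is delegated to OpenBabel via
# ChemmineR.
smiles_atom_graph <- function(smiles) {
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) stop("cannot parse SMILES: ", smiles, call. = FALSE)
  )
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  if (nrow(ab) == 0) stop("cannot parse SMILES: ", smiles, call. = FALSE)
  symbol <- sub("_.*$", "", rownames(ab))
  bonds <- if (is.null(bb) || nrow(bb) == 0) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  list(symbol = symbol, bonds = bonds)
}

#' Perfluorinated chain length of a PFAS structure
#'
#' Chain length is the maximum contiguous number of fully fluorinated
#' carbons. A carbon is fully fluorinated when it carries at least one
#' fluorine and no hydrogens (implicit or explicit): every position not used
#' by the backbone or a functional group is fluorinated. Carbons bonded to
#' heteroatoms still qualify as long as they are H-free and F-bearing, so
#' the sulfonate carbon of PFOS counts (PFOS -> 8) while the fluorine-free
#' carboxyl carbon of PFOA does not (PFOA -> 7). Contiguity is the longest
#' simple path in the carbon-carbon adjacency graph restricted to qualifying
#' carbons, which handles branched structures deterministically.
#'
#' @param smiles SMILES string; `NA` propagates to `NA` so that chemicals
#'   without structures are excluded rather than misplaced at zero.
#' @return Integer chain length (0 when no carbon qualifies), or `NA` for a
#'   missing structure.
#' @examples
#' chain_length("OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F")
#' # PFOA -> 7
#' @export
chain_length <- function(smiles) {
  if (length(smiles) != 1) {
    return(vapply(smiles, chain_length, integer(1), USE.NAMES = FALSE))
  }
  if (is.na(smiles)) return(NA_integer_)
  g <- smiles_atom_graph(smiles)
  n <- length(g$symbol)
  # bond-order sum per atom; carbon valence 4 => any shortfall is implicit H
  order_sum <- rep(0L, n)
  for (i in seq_len(nrow(g$bonds))) {
    b <- g$bonds[i, ]
    order_sum[b$a1] <- order_sum[b$a1] + b$order
    order_sum[b$a2] <- order_sum[b$a2] + b$order
  }
  neighbours <- vector("list", n)
  for (i in seq_len(nrow(g$bonds))) {
    b <- g$bonds[i, ]
    neighbours[[b$a1]] <- c(neighbours[[b$a1]], b$a2)
    neighbours[[b$a2]] <- c(neighbours[[b$a2]], b$a1)
  }
  qualifies <- vapply(seq_len(n), function(i) {
    if (g$symbol[i] != "C") return(FALSE)
    if (order_sum[i] < 4L) return(FALSE)  # implicit hydrogen present
    nb_sym <- g$symbol[neighbours[[i]]]
    if (any(nb_sym == "H")) return(FALSE)
    any(nb_sym == "F")
  }, logical(1))
  keep <- which(qualifies)
  if (length(keep) == 0) return(0L)
  # adjacency among qualifying carbons
  adj <- lapply(keep, function(i) intersect(neighbours[[i]], keep))
  names(adj) <- as.character(keep)
  longest_simple_path(keep, adj)
}

# Longest simple path (node count) by exhaustive DFS; qualifying subgraphs
# of PFAS are tiny so this is exact and fast.
longest_simple_path <- function(nodes, adj) {
  best <- 0L
  dfs <- function(node, visited) {
    best <<- max(best, length(visited))
    for (nxt in adj[[as.character(node)]]) {
      if (!nxt %in% visited) dfs(nxt, c(visited, nxt))
    }
  }
  for (start in nodes) dfs(start, start)
  as.integer(best)
}

#' Packaged PFAS roster
#'
#' Returns the path of the packaged roster of 31 PFAS that have
#' biomonitoring data, in vitro bioactivity data and blood-to-plasma
#' partitioning information. Identities (DTXSID, CASRN, name, abbreviation)
#' follow the published roster; formulas and SMILES are standard structures
#' for these well-characterized substances; blood-to-plasma ratios are left
#' missing so the 0.5 default applies; half-life classes follow the QSAR
#' classification (all > 2 months except PFPeA, < 1 week).
#'
#' @return File path of the roster CSV.
#' @export
pfas_roster_path <- function() {
  system.file("extdata", "pfas_roster.csv", package = "bcbcr",
              mustWork = TRUE)
}
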