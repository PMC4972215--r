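#' The seven scored sugars, in canonical trait-table column order
#'
#' The trait table is a CSV with one row per species and columns: `species`
#' (matching tree tip labels up to whitespace/underscore differences),
#' `cell_diameter_low_min` and `cell_diameter_low_max` (the reported range of
#' the lower cell-diameter axis, in micrometres), and one fermentation-code
#' column per sugar listed here. Codes use the standard taxonomic-monograph
#' vocabulary: `+` positive, `-` negative, `s` slow, `w` weak, `±`/`+-` or
#' `v` variable, empty/NA not reported.
#'
#' @format character vector of length 7.
#' @export
SUGARS <- c("glucose", "galactose", "sucrose", "maltose",
            "lactose", "raffinose", "trehalose")

.FERM_POSITIVE <- c("+", "s", "w")
.FERM_NEGATIVE <- c("-", "−", "±", "+-", "-+", "v", "")

#' Fermentation versatility from per-sugar test codes
#'
#' Counts the sugars a species can ferment: positive (`+`), slow (`s`) and
#' weak (`w`) responses qualify; variable responses (`±`, `v`) and negatives
#' do not, and sugars with no reported test are treated (conservatively) as
#' negative. The result is the ordinal versatility score used throughout
#' the analysis (observed range 0-6 in the yeast data, theoretical 0-7).
#'
#' @param codes character vector of fermentation codes (one per sugar); NA =
#'   not reported.
#' @param species optional species name used in error messages.
#' @return integer count in `[0, length(codes)]`.
#' @export
versatility_from_codes <- function(codes, species = NULL) {
  codes <- trimws(as.character(codes))
  codes[is.na(codes)] <- ""
  known <- c(.FERM_POSITIVE, .FERM_NEGATIVE)
  bad <- which(!(tolower(codes) %in% known))
  if (length(bad)) {
    who <- if (is.null(species)) "" else paste0(" for species '", species, "'")
    stop("unknown fermentation code '", codes[bad[1L]], "'", who,
         " (sugar #", bad[1L], ")", call. = FALSE)
  }
  sum(tolower(codes) %in% .FERM_POSITIVE)
}

#' Cell size from a reported diameter range
#'
#' The working cell-size value is the midpoint of the reported range of the
#' lower diameter axis (yeast cells are typically asymmetric, so the lower
#' axis is the comparable one).
#'
#' @param low,high range endpoints in micrometres, `0 < low <= high`.
#' @return numeric midpoint in micrometres.
#' @export
cell_size_from_range <- function(low, high) {
  low <- as.numeric(low)
  high <- as.numeric(high)
  if (any(!is.finite(low)) || any(!is.finite(high)) ||
      any(low <= 0) || any(high < low)) {
    stop("invalid diameter range: need 0 < low <= high", call. = FALSE)
  }
  (low + high) / 2
}

#' Read and encode a species trait table
#'
#' Reads the CSV (see the schema in the package docs), derives `cell_size`
#' (range midpoint, um), `log_cell_size` (natural log) and `versatility`
#' (ordinal fermentation count) per species, and normalizes species names
#' (trimmed, spaces unified to underscores) for matching against tree tips.
#'
#' @param path path to the CSV file.
#' @return a data.frame with the raw columns plus the derived ones.
#' @export
read_trait_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("species", "cell_diameter_low_min", "cell_diameter_low_max", SUGARS)
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("trait table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$species <- normalize_species(df$species)
  if (anyDuplicated(df$species)) {
    stop("duplicate species in trait table: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "),
         call. = FALSE)
  }
  derive_trait_columns(df)
}

#' Derive cell-size and versatility columns on a raw trait table
#'
#' Adds `cell_size` (range midpoint, um), `log_cell_size` and `versatility`
#' to a data.frame following the trait-table schema (see [SUGARS]); applied
#' automatically by [read_trait_table()] and [align_traits()].
#'
#' @param df a trait-table data.frame.
#' @return the data.frame with the derived columns appended.
#' @export
derive_trait_columns <- function(df) {
  if (all(c("cell_diameter_low_min", "cell_diameter_low_max") %in% names(df)) &&
      !"cell_size" %in% names(df)) {
    df$cell_size <- cell_size_from_range(df$cell_diameter_low_min,
                                         df$cell_diameter_low_max)
    df$log_cell_size <- log(df$cell_size)
  }
  if (all(SUGARS %in% names(df)) && !"versatility" %in% names(df)) {
    df$versatility <- vapply(seq_len(nrow(df)), function(i) {
      versatility_from_codes(unlist(df[i, SUGARS]), species = df$species[i])
    }, integer(1L))
  }
  df
}

#' Normalize species names for tree/table matching
#' @param x character vector of species names.
#' @return character vector with trimmed whitespace and spaces as underscores.
#' @export
normalize_species <- function(x) {
  gsub("[ ]+", "_", trimws(as.character(x)))
}

#' Align a tree with a trait table
#'
#' Prunes the tree to the species shared with the table and returns trait
#' vectors ordered exactly as the pruned tree's tips (the ordering contract
#' every downstream statistic relies on). Species present on only one side
#' are reported via `message()` and in the returned object.
#'
#' @param phy a `"phylo"` tree.
#' @param table a trait table from [read_trait_table()] (or any data.frame
#'   with a `species` column and per-species trait columns).
#' @param quiet suppress the dropped-species message.
#' @return a list with elements `tree` (pruned), `table` (reordered rows),
#'   `dropped_from_tree`, `dropped_from_table`, and a numeric vector per
#'   derived trait column present (`cell_size`, `log_cell_size`,
#'   `versatility`), each named by tip label.
#' @export
align_traits <- function(phy, table, quiet = FALSE) {
  stopifnot(inherits(phy, "phylo"), is.data.frame(table), "species" %in% names(table))
  table <- derive_trait_columns(table)
  table$species <- normalize_species(table$species)
  tips <- normalize_species(phy$tip.label)
  phy$tip.label <- tips
  shared <- intersect(tips, table$species)
  if (length(shared) < 2L) stop("fewer than 2 species shared between tree and table",
                                call. = FALSE)
  dropped_tree <- setdiff(tips, shared)
  dropped_table <- setdiff(table$species, shared)
  if (!quiet && (length(dropped_tree) || length(dropped_table))) {
    if (length(dropped_tree)) message("dropped from tree (no trait data): ",
                                      paste(dropped_tree, collapse = ", "))
    if (length(dropped_table)) message("dropped from table (not in tree): ",
                                       paste(dropped_table, collapse = ", "))
  }
  tree <- if (length(dropped_tree)) prune_to_taxa(phy, shared) else phy
  table <- table[match(tree$tip.label, table$species), , drop = FALSE]
  rownames(table) <- NULL
  out <- list(tree = tree, table = table,
              dropped_from_tree = dropped_tree,
              dropped_from_table = dropped_table)
  for (col in c("cell_size", "log_cell_size", "versatility")) {
    if (col %in% names(table)) {
      out[[col]] <- setNames(as.numeric(table[[col]]), tree$tip.label)
    }
  }
  out
}

#' Double-log transform for cell size
#'
#' `log(log(x))`: the transform chain used for the PGLS response. Requires
#' cell sizes above 1 um so the inner log is positive.
#'
#' @param x positive numeric vector (um), all values > 1.
#' @return numeric vector.
#' @export
loglog <- function(x) {
  if (any(x <= 1)) stop("double-log transform requires values > 1", call. = FALSE)
  log(log(x))
}
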