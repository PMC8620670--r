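# Checklist data model: loading, validation, status algebra and tabulations.

#' Controlled vocabularies for checklist fields
#'
#' Category tokens accepted (after lower-casing) in each checklist column.
#' `lifeform_levels` are the canonical lifeforms stored on a checklist;
#' additional growth-form tokens in raw files are mapped onto them via the
#' `lifeform_map` argument of [read_checklist()].
#'
#' @format Character vectors of allowed tokens.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
lifeform_levels <- c("annual", "biennial", "perennial", "woody", "other")

#' @rdname vocabularies
#' @export
pathway_levels <- c("ornamental", "forage", "medicinal", "food",
                    "unintentional", "natural", "unknown", "other")

#' @rdname vocabularies
#' @export
status_levels <- c("casual", "naturalized", "invasive")

#' @rdname vocabularies
#' @export
tdwg_regions <- c("europe", "africa", "temperate asia", "tropical asia",
                  "australasia", "pacific", "america", "antarctic", "unknown")

# Default mapping of extra growth-form tokens onto canonical lifeforms.
# Shrubs and trees are woody; vines and aquatics are lumped as "other"
# since a vine may be herbaceous and aquatics span growth forms.
default_lifeform_map <- c(shrub = "woody", tree = "woody",
                          vine = "other", aquatic = "other")

required_columns <- c("species", "family", "genus", "lifeform",
                      "origin", "pathway", "status")

canon <- function(x) tolower(trimws(x))

#' Construct a checklist from a data frame
#'
#' Validates a species table and returns a `checklist` object. One row per
#' species; the `status` column stores the highest invasion stage the species
#' has attained (`casual`, `naturalized` or `invasive`) — nested assemblages
#' are always derived, never stored, so the stage flags cannot disagree.
#'
#' @param df data frame with columns `species`, `family`, `genus`,
#'   `lifeform`, `origin`, `pathway`, `status`. `origin` is either a
#'   semicolon-separated string of TDWG level-1 region names or a list column
#'   of character vectors.
#' @param lifeform_map named character vector mapping extra growth-form
#'   tokens (e.g. `shrub`, `tree`) onto canonical lifeforms; overrides and
#'   extends the built-in mapping.
#' @return A `checklist`: a data frame with columns `species`, `family`,
#'   `genus`, `lifeform`, `origins` (list of character vectors), `pathway`,
#'   `status`, all category tokens canonicalized to lower case.
#' @export
as_checklist <- function(df, lifeform_map = NULL) {
  stopifnot(is.data.frame(df))
  cols <- required_columns
  if (!is.null(df[["origins"]]) && is.null(df[["origin"]]))
    names(df)[names(df) == "origins"] <- "origin"
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("checklist is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  map <- default_lifeform_map
  if (!is.null(lifeform_map)) {
    lifeform_map <- stats::setNames(canon(lifeform_map), canon(names(lifeform_map)))
    bad <- setdiff(lifeform_map, lifeform_levels)
    if (length(bad))
      stop("lifeform_map targets must be canonical lifeforms; offending: ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    map[names(lifeform_map)] <- lifeform_map
  }

  species <- trimws(as.character(df$species))
  n <- length(species)
  if (any(!nzchar(species)))
    stop("empty species name at row(s) ",
         paste(which(!nzchar(species)), collapse = ", "), call. = FALSE)
  dup <- duplicated(species)
  if (any(dup)) {
    first <- species[dup][1L]
    stop(sprintf("duplicate species name '%s' at row(s) %s", first,
                 paste(which(species == first), collapse = ", ")),
         call. = FALSE)
  }

  lifeform <- canon(as.character(df$lifeform))
  mapped <- !is.na(match(lifeform, names(map)))
  lifeform[mapped] <- map[lifeform[mapped]]
  check_enum(lifeform, lifeform_levels, "lifeform")

  pathway <- canon(as.character(df$pathway))
  check_enum(pathway, pathway_levels, "pathway")

  status <- canon(as.character(df$status))
  check_enum(status, status_levels, "status")

  origin <- df$origin
  if (!is.list(origin))
    origin <- strsplit(as.character(origin), ";", fixed = TRUE)
  origins <- lapply(origin, function(x) unique(canon(x[nzchar(trimws(x))])))
  empty <- lengths(origins) == 0L
  if (any(empty))
    stop("empty origin set at row(s) ",
         paste(which(empty), collapse = ", "), call. = FALSE)
  bad_region <- vapply(origins, function(x) any(!x %in% tdwg_regions), logical(1))
  if (any(bad_region)) {
    rows <- which(bad_region)
    bad <- setdiff(unique(unlist(origins[rows])), tdwg_regions)
    stop(sprintf("unknown origin region(s) %s at row(s) %s; allowed: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(rows, collapse = ", "),
                 paste(tdwg_regions, collapse = ", ")), call. = FALSE)
  }

  out <- data.frame(species = species,
                    family = canon(as.character(df$family)),
                    genus = canon(as.character(df$genus)),
                    lifeform = lifeform,
                    pathway = pathway,
                    status = status,
                    stringsAsFactors = FALSE)
  out$origins <- origins
  out <- out[c("species", "family", "genus", "lifeform", "origins",
               "pathway", "status")]
  class(out) <- c("checklist", "data.frame")
  out
}

check_enum <- function(x, levels, what) {
  bad <- !x %in% levels
  if (any(bad))
    stop(sprintf("unknown %s token(s) %s at row(s) %s; allowed: %s",
                 what, paste(sQuote(unique(x[bad])), collapse = ", "),
                 paste(which(bad), collapse = ", "),
                 paste(levels, collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' Read a species checklist from CSV
#'
#' Expects a UTF-8, comma-delimited file with header
#' `species,family,genus,lifeform,origin,pathway,status`; `origin` is a
#' semicolon-separated list of TDWG level-1 region names. Tokens are
#' case-insensitive and canonicalized to lower case. Lifeform normalization
#' (biennial to perennial) is *not* applied on read; see
#' [normalize_lifeform()].
#'
#' @param path path to the CSV file.
#' @param sep field delimiter (default comma).
#' @inheritParams as_checklist
#' @return A [as_checklist()] validated `checklist`.
#' @examples
#' f <- system.file("extdata", "mini_checklist.csv", package = "alienflora")
#' read_checklist(f)
#' @export
read_checklist <- function(path, sep = ",", lifeform_map = NULL) {
  if (!file.exists(path)) stop("checklist file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = TRUE)
  as_checklist(df, lifeform_map = lifeform_map)
}

#' Write a checklist back to CSV
#'
#' Inverse of [read_checklist()]: the `origins` list column is collapsed to a
#' semicolon-separated `origin` field.
#'
#' @param x a `checklist`.
#' @param path output path.
#' @export
write_checklist <- function(x, path) {
  stopifnot(inherits(x, "checklist"))
  df <- as.data.frame(x)
  df$origin <- vapply(df$origins, paste, character(1), collapse = ";")
  df$origins <- NULL
  df <- df[c("species", "family", "genus", "lifeform", "origin",
             "pathway", "status")]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.checklist <- function(x, ...) {
  cat(sprintf("Alien species checklist: %d species, %d families\n",
              nrow(x), length(unique(x$family))))
  tab <- table(factor(x$status, levels = status_levels))
  cat(sprintf("  status (highest stage attained): casual %d, naturalized %d, invasive %d\n",
              tab[["casual"]], tab[["naturalized"]], tab[["invasive"]]))
  invisible(x)
}

#' Normalize lifeforms (biennials classified as perennials)
#'
#' Biennial species are rare in alien floras; following common practice they
#' are lumped with perennials before tabulation. All other lifeforms are
#' unchanged; the operation is idempotent.
#'
#' @param x a `checklist` or a character vector of lifeform tokens.
#' @return Object of the same type with `biennial` replaced by `perennial`.
#' @export
normalize_lifeform <- function(x) {
  if (inherits(x, "checklist")) {
    x$lifeform <- normalize_lifeform(x$lifeform)
    return(x)
  }
  x[x == "biennial"] <- "perennial"
  x
}

#' Derive the five nested assemblages from a checklist
#'
#' The status column stores the highest attained invasion stage, so the
#' nested sets follow by algebra: every species is alien; naturalized species
#' are those with status `naturalized` or `invasive`; invasive species those
#' with status `invasive`. Casual aliens are alien-but-not-naturalized, and
#' NNI (naturalized but not invasive) is naturalized minus invasive.
#'
#' @param checklist a `checklist`.
#' @return An `assemblage_set`: a named list of species-name character
#'   vectors `alien`, `casual`, `naturalized`, `nni`, `invasive` satisfying
#'   `invasive` ⊆ `naturalized` ⊆ `alien`, `casual = alien \ naturalized`
#'   and `nni = naturalized \ invasive`.
#' @examples
#' f <- system.file("extdata", "mini_checklist.csv", package = "alienflora")
#' derive_assemblages(read_checklist(f))
#' @export
derive_assemblages <- function(checklist) {
  stopifnot(inherits(checklist, "checklist"))
  sp <- checklist$species
  st <- checklist$status
  out <- list(alien       = sp,
              casual      = sp[st == "casual"],
              naturalized = sp[st %in% c("naturalized", "invasive")],
              nni         = sp[st == "naturalized"],
              invasive    = sp[st == "invasive"])
  class(out) <- "assemblage_set"
  validate_assemblage_set(out)
  out
}

validate_assemblage_set <- function(x) {
  stopifnot(inherits(x, "assemblage_set"))
  with(x, {
    stopifnot(all(invasive %in% naturalized),
              all(naturalized %in% alien),
              setequal(casual, setdiff(alien, naturalized)),
              setequal(nni, setdiff(naturalized, invasive)),
              length(casual) + length(naturalized) == length(alien),
              length(nni) + length(invasive) == length(naturalized))
  })
  invisible(x)
}

#' @export
print.assemblage_set <- function(x, ...) {
  cat("Nested invasion-stage assemblages (species counts):\n")
  for (nm in assemblage_names)
    cat(sprintf("  %-12s %d\n", nm, length(x[[nm]])))
  invisible(x)
}

# Stable assemblage order; index also drives per-assemblage sub-seeds.
assemblage_names <- c("alien", "casual", "naturalized", "nni", "invasive")

#' Tabulate checklist composition for an assemblage
#'
#' Counts and proportions of species per category of `field` within an
#' assemblage. For `family`, `lifeform` and `pathway` every species falls in
#' exactly one category and proportions sum to 1. For `origin`, a species
#' contributes one count to *each* of its native regions (TDWG regions are
#' not exclusive for a species), so origin proportions may sum to more than
#' 1. Proportions are returned at full precision; round for display.
#'
#' @param checklist a `checklist`.
#' @param field one of `"family"`, `"lifeform"`, `"origin"`, `"pathway"`.
#' @param assemblage character vector of species names (subset of the
#'   checklist); defaults to all species (the alien assemblage).
#' @return Data frame with columns `field`, `category`, `count`,
#'   `proportion`, sorted by decreasing count.
#' @export
tabulate_by <- function(checklist, field = c("family", "lifeform", "origin", "pathway"),
                        assemblage = NULL) {
  stopifnot(inherits(checklist, "checklist"))
  field <- match.arg(field)
  if (is.null(assemblage)) assemblage <- checklist$species
  if (length(assemblage) == 0L) stop("empty assemblage", call. = FALSE)
  extra <- setdiff(assemblage, checklist$species)
  if (length(extra))
    stop("assemblage contains species absent from the checklist: ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  rows <- checklist[checklist$species %in% assemblage, ]
  vals <- if (field == "origin") unlist(rows$origins) else rows[[field]]
  tab <- table(vals)
  out <- data.frame(field = field,
                    category = names(tab),
                    count = as.integer(tab),
                    proportion = as.numeric(tab) / length(assemblage),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$category), , drop = FALSE]
}

#' Per-family naturalization and invasion transition rates
#'
#' For each family, the fraction of its alien species that have naturalized
#' (`rate_nat`) and the fraction of its naturalized species that have become
#' invasive (`rate_inv`). A family with no naturalized species has an
#' undefined invasion rate, reported as `NA` (never 0).
#'
#' @param checklist a `checklist`.
#' @param families family names to report; default all families present.
#'   Requesting an absent family is an error.
#' @return Data frame with columns `family`, `n_alien`, `n_naturalized`,
#'   `n_invasive`, `rate_nat`, `rate_inv`.
#' @export
transition_rates <- function(checklist, families = NULL) {
  stopifnot(inherits(checklist, "checklist"))
  present <- unique(checklist$family)
  if (is.null(families)) families <- sort(present)
  absent <- setdiff(families, present)
  if (length(absent))
    stop("family not present in checklist: ",
         paste(absent, collapse = ", "), call. = FALSE)
  st <- checklist$status
  res <- lapply(families, function(f) {
    in_f <- checklist$family == f
    n_alien <- sum(in_f)
    n_nat <- sum(in_f & st %in% c("naturalized", "invasive"))
    n_inv <- sum(in_f & st == "invasive")
    data.frame(family = f, n_alien = n_alien, n_naturalized = n_nat,
               n_invasive = n_inv,
               rate_nat = if (n_alien > 0L) n_nat / n_alien else NA_real_,
               rate_inv = if (n_nat > 0L) n_inv / n_nat else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
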