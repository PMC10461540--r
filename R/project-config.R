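# Colour roles for class-entry categories (border colours in the renderer).
CLASS_CATEGORY_COLOURS <- c(core = "green", custom = "blue",
                            misc = "orange", unknown = "grey")

# Misc categories offered to every site by default: frequent non-target
# sound sources in field recordings.
DEFAULT_MISC_CLASSES <- c("Human", "Insect", "Weather noise", "Unknown")

read_bom_csv <- function(path, ...) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  fileEncoding = "UTF-8-BOM", check.names = FALSE, ...)
}

#' Load per-site species lists
#'
#' Reads `species_list.csv`: one column per study site, the header row
#' holding the site names. Columns may be ragged (different species counts
#' per site); blank cells are dropped. Species may be stored in any order in
#' the file - each site's list is deduplicated and sorted alphabetically at
#' load time.
#'
#' @param path Path to a species-list CSV (UTF-8, BOM tolerated).
#' @return An object of class `"species_lists"`: a named list of sorted
#'   character vectors, one per site, in file column order.
#' @export
load_species_lists <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("species list file not found: '%s'", path), call. = FALSE)
  }
  df <- read_bom_csv(path, colClasses = "character")
  sites <- names(df)
  if (anyDuplicated(sites)) {
    stop(sprintf("duplicate site column(s) in '%s': %s", path,
                 paste(unique(sites[duplicated(sites)]), collapse = ", ")),
         call. = FALSE)
  }
  lists <- lapply(df, function(col) {
    col <- trimws(col)
    sort(unique(col[!is.na(col) & nzchar(col)]))
  })
  structure(lists, class = "species_lists")
}

#' @export
print.species_lists <- function(x, ...) {
  cat(sprintf("<species lists> %d site(s)\n", length(x)))
  for (s in names(x)) cat(sprintf("  %s: %d species\n", s, length(x[[s]])))
  invisible(x)
}

#' Merge uploaded species lists into existing ones
#'
#' Site columns of `uploaded` whose names are not already present are
#' appended; existing site lists are never modified. Merging the same upload
#' twice therefore equals merging it once.
#'
#' @param existing,uploaded `"species_lists"` objects.
#' @return The merged `"species_lists"`.
#' @export
merge_species_lists <- function(existing, uploaded) {
  stopifnot(inherits(existing, "species_lists"),
            inherits(uploaded, "species_lists"))
  new_sites <- setdiff(names(uploaded), names(existing))
  out <- c(unclass(existing), unclass(uploaded)[new_sites])
  structure(out, class = "species_lists")
}

#' Build the class list for an annotation session
#'
#' Assembles the clickable class list: the selected site's species (category
#' `core`, green border), then miscellaneous categories (`misc`, orange),
#' then manually added classes (`custom`, blue). A label whose class is in
#' none of these resolves to category `unknown` (grey) at render time.
#'
#' @param lists A [load_species_lists()] result.
#' @param site Site name; must be one of `names(lists)`.
#' @param custom Character vector of manually added classes.
#' @param misc Character vector of miscellaneous categories (defaults to a
#'   small configurable set of common non-target sources).
#' @return A data frame of class `"class_list"` with columns `name`,
#'   `category` and `display_code` (initially equal to `name`; see
#'   [apply_bto_codes()]).
#' @export
build_class_list <- function(lists, site, custom = character(),
                             misc = DEFAULT_MISC_CLASSES) {
  stopifnot(inherits(lists, "species_lists"))
  if (!site %in% names(lists)) {
    stop(sprintf("unknown site '%s'; available sites: %s", site,
                 paste(names(lists), collapse = ", ")), call. = FALSE)
  }
  name <- c(lists[[site]], misc, custom)
  category <- c(rep("core", length(lists[[site]])),
                rep("misc", length(misc)),
                rep("custom", length(custom)))
  structure(data.frame(name = name, category = category,
                       display_code = name, stringsAsFactors = FALSE),
            class = c("class_list", "data.frame"))
}

#' Add a class to the class list
#'
#' Appends `name` with category `custom`. Matching is case-sensitive and
#' exact; adding a class already present raises an error (the class is
#' already in the list) and leaves the list unchanged.
#'
#' @param entries A `"class_list"` data frame.
#' @param name Non-empty class name.
#' @return The extended class list.
#' @export
add_class <- function(entries, name) {
  stopifnot(inherits(entries, "class_list"))
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("class name must be a non-empty string", call. = FALSE)
  }
  if (name %in% entries$name) {
    stop(sprintf("class '%s' is already present in the list", name),
         call. = FALSE)
  }
  out <- rbind(entries, data.frame(name = name, category = "custom",
                                   display_code = name,
                                   stringsAsFactors = FALSE))
  structure(out, class = c("class_list", "data.frame"))
}

#' Remove a class from the class list
#'
#' @param entries A `"class_list"` data frame.
#' @param name Class name to remove (case-sensitive exact match).
#' @return The class list without that entry.
#' @export
remove_class <- function(entries, name) {
  stopifnot(inherits(entries, "class_list"))
  i <- which(entries$name == name)
  if (length(i) == 0) {
    stop(sprintf("class '%s' is not in the list", name), call. = FALSE)
  }
  out <- entries[-i, ]
  rownames(out) <- NULL
  structure(out, class = c("class_list", "data.frame"))
}

#' Look up the colour role of a class
#'
#' @param entries A `"class_list"` data frame.
#' @param name Class name (e.g. from a saved label).
#' @return The border colour: green for core, blue for custom, orange for
#'   misc, grey for a class not in the list.
#' @export
class_colour <- function(entries, name) {
  i <- match(name, entries$name)
  cat_ <- ifelse(is.na(i), "unknown", entries$category[i])
  unname(CLASS_CATEGORY_COLOURS[cat_])
}

#' Load a BTO species-code lookup table
#'
#' The British Trust for Ornithology publishes short letter codes for bird
#' species. The lookup CSV has two columns, `bto_code` and `species_name`.
#'
#' @param path Path to `bto_codes.csv` (UTF-8, BOM tolerated).
#' @return A data frame with columns `bto_code` and `species_name`.
#' @export
load_bto_codes <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("BTO code file not found: '%s'", path), call. = FALSE)
  }
  df <- read_bom_csv(path, colClasses = "character")
  missing <- setdiff(c("bto_code", "species_name"), names(df))
  if (length(missing) > 0) {
    stop(sprintf("BTO lookup '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Apply BTO display codes to a class list
#'
#' Sets each entry's `display_code` to its BTO code where the class name has
#' an exact match in the lookup's `species_name` column; unmatched names
#' (non-species classes, typos) keep their name as display code. The `name`
#' field itself is never altered, so labels continue to store full class
#' names. The operation is idempotent.
#'
#' @param entries A `"class_list"` data frame.
#' @param lookup A data frame with columns `bto_code` and `species_name`
#'   (e.g. from [load_bto_codes()]).
#' @return The class list with updated `display_code`s.
#' @export
apply_bto_codes <- function(entries, lookup) {
  stopifnot(inherits(entries, "class_list"))
  if (!is.data.frame(lookup) ||
      !all(c("bto_code", "species_name") %in% names(lookup))) {
    stop("`lookup` must have columns bto_code and species_name",
         call. = FALSE)
  }
  i <- match(entries$name, lookup$species_name)
  entries$display_code <- ifelse(is.na(i), entries$name, lookup$bto_code[i])
  entries
}

LOCATION_KNOWN_COLUMNS <- c("recorder_name", "lat", "long", "location_name",
                            "location_county", "habitat_type",
                            "dist_to_coastline")

#' Load recorder/site metadata
#'
#' Reads `location_list.csv`: one row per deployed recorder with site
#' metadata (coordinates, site name, county, habitat type, distance to the
#' nearest coastline in km). Any field other than `recorder_name` may be
#' blank. Extra columns are preserved verbatim and reported alongside the
#' known fields.
#'
#' @param path Path to `location_list.csv` (UTF-8, BOM tolerated).
#' @return A data frame of class `"location_list"` with the known columns
#'   first; extra column names are recorded in the `"extra_columns"`
#'   attribute.
#' @export
load_locations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("location list file not found: '%s'", path), call. = FALSE)
  }
  df <- read_bom_csv(path, colClasses = "character")
  if (!"recorder_name" %in% names(df)) {
    stop(sprintf("location list '%s' is missing the recorder_name column",
                 path), call. = FALSE)
  }
  if (any(!nzchar(trimws(df$recorder_name)))) {
    stop(sprintf("location list '%s' has row(s) with empty recorder_name",
                 path), call. = FALSE)
  }
  for (cl in setdiff(LOCATION_KNOWN_COLUMNS, names(df))) df[[cl]] <- ""
  df[is.na(df)] <- ""
  extras <- setdiff(names(df), LOCATION_KNOWN_COLUMNS)
  df <- df[c(LOCATION_KNOWN_COLUMNS, extras)]
  structure(df, class = c("location_list", "data.frame"),
            extra_columns = extras)
}

#' Match an audio file to its recorder's site metadata
#'
#' Parses the recorder token from the file name and looks it up in the
#' location list by exact match. Linking is best-effort: an unparsable name
#' or unknown recorder returns `NULL` with a warning rather than an error.
#'
#' @param file_name Audio file name following the recorder convention.
#' @param locations A [load_locations()] result.
#' @return A one-row list of site metadata (class `"site_metadata"`, with an
#'   `extras` element of the extra columns), or `NULL`.
#' @export
match_recorder <- function(file_name, locations) {
  stopifnot(inherits(locations, "location_list"))
  id <- withCallingHandlers(parse_filename(file_name),
                            warning = function(w) invokeRestart("muffleWarning"))
  if (is.null(id)) {
    warning(sprintf("cannot parse recorder from '%s'", file_name),
            call. = FALSE)
    return(NULL)
  }
  i <- which(locations$recorder_name == id$recorder)
  if (length(i) == 0) {
    warning(sprintf("recorder '%s' not found in the location list",
                    id$recorder), call. = FALSE)
    return(NULL)
  }
  row <- as.list(locations[i[1], LOCATION_KNOWN_COLUMNS])
  extras <- attr(locations, "extra_columns")
  row$extras <- as.list(locations[i[1], extras, drop = FALSE])
  structure(row, class = "site_metadata")
}
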