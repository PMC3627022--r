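#' Life-stage classification rules by growth form
#'
#' The dbh cut-offs defining sapling, juvenile and adult stages for each of
#' the five growth forms: shrubs (S, max height <= 5 m), small understory
#' trees (US, 5-10 m), large understory trees (UL, 10-20 m), small canopy
#' trees (CS, 20-30 m) and large canopy trees (CL, > 30 m). The printed
#' one-decimal intervals (e.g. CL: sapling 1.0-8.0, juvenile 8.1-15.0,
#' adult > 15.0) are interpreted as half-open intervals
#' `[lower, next_lower)` so that classification is total on dbh >= 1: the
#' 0.1-cm gaps in the printed table reflect measurement resolution, not real
#' gaps.
#'
#' @return A `data.frame` with columns `growth_form`, `sapling_lower`,
#'   `juvenile_lower` and `adult_lower` (cm); a stem is a sapling on
#'   `[sapling_lower, juvenile_lower)`, a juvenile on
#'   `[juvenile_lower, adult_lower)`, and an adult at or above `adult_lower`.
#' @examples
#' stageRules()
#' classifyStage(8.1, "CL")   # juvenile
#' @export
stageRules <- function() {
  data.frame(
    growth_form    = c("S", "US", "UL", "CS", "CL"),
    sapling_lower  = c(1.0, 1.0, 1.0, 1.0, 1.0),
    juvenile_lower = c(1.6, 2.1, 2.6, 5.1, 8.1),
    adult_lower    = c(2.1, 4.1, 6.1, 10.1, 15.1))
}

#' Classify stems into life stages by dbh
#'
#' Assigns each stem to the sapling, juvenile or adult stage according to its
#' dbh and the growth form of its species. Vectorized over `dbh` and
#' `growthForm` (recycled).
#'
#' @param dbh stem diameter at breast height (cm); must be >= 1.
#' @param growthForm growth form code, one of `"S"`, `"US"`, `"UL"`, `"CS"`,
#'   `"CL"`.
#' @param rules a rule table as returned by [stageRules()].
#' @return Character vector of `"sapling"`, `"juvenile"`, `"adult"`.
#' @examples
#' classifyStage(c(2.1, 5.0), c("S", "CS"))  # adult, sapling
#' @export
classifyStage <- function(dbh, growthForm, rules = stageRules()) {
  n <- max(length(dbh), length(growthForm))
  dbh <- rep_len(as.numeric(dbh), n)
  growthForm <- rep_len(as.character(growthForm), n)
  if (any(is.na(dbh)) || any(dbh < 1))
    stop("dbh must be >= 1 cm for stage classification")
  idx <- match(growthForm, rules$growth_form)
  if (anyNA(idx))
    stop("unknown growth form(s): ",
         paste(unique(growthForm[is.na(idx)]), collapse = ", "))
  stage <- rep("sapling", n)
  stage[dbh >= rules$juvenile_lower[idx]] <- "juvenile"
  stage[dbh >= rules$adult_lower[idx]] <- "adult"
  stage
}

#' Read and validate a mapped stem census table
#'
#' Reads a delimited stem table with header columns `tag,species,x,y,dbh`
#' (coordinates in metres from the plot corner, dbh in cm) and validates
#' every record against the observation window and the dbh >= 1 cm census
#' threshold. Row order and count are preserved.
#'
#' @param path path to the CSV file.
#' @param window the plot [Window] records must fall inside.
#' @return A `data.frame` of validated stem records.
#' @seealso [writeStemTable()] for the inverse operation.
#' @export
readStemTable <- function(path, window = Window()) {
  stems <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("tag", "species", "x", "y", "dbh")
  missing <- setdiff(required, names(stems))
  if (length(missing))
    stop("stem table is missing column(s): ", paste(missing, collapse = ", "))
  validateStems(stems, window)
  stems
}

validateStems <- function(stems, window) {
  if (anyDuplicated(stems$tag))
    stop("duplicate tag(s): ",
         paste(unique(stems$tag[duplicated(stems$tag)]), collapse = ", "))
  bad <- which(is.na(stems$dbh) | stems$dbh < 1)
  if (length(bad))
    stop(sprintf("row %d: field 'dbh' is %s (must be >= 1 cm)",
                 bad[1], stems$dbh[bad[1]]))
  for (f in c("x", "y")) {
    v <- stems[[f]]
    lo <- if (f == "x") window@xMin else window@yMin
    hi <- if (f == "x") window@xMax else window@yMax
    bad <- which(is.na(v) | v < lo | v > hi)
    if (length(bad))
      stop(sprintf("row %d: field '%s' is %s, outside window [%g, %g]",
                   bad[1], f, v[bad[1]], lo, hi))
  }
  invisible(TRUE)
}

#' Write a stem table
#'
#' Writes stem records in the canonical `tag,species,x,y,dbh` CSV layout
#' read by [readStemTable()]; reading and re-writing a canonical file
#' round-trips byte-identically.
#'
#' @param stems a stem `data.frame`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStemTable <- function(stems, path) {
  write.csv(stems[, c("tag", "species", "x", "y", "dbh")], path,
            quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a point pattern from stem records
#'
#' Extracts the stems of one species (optionally one life stage) as a marked
#' [PointPattern], classifying stages with [classifyStage()].
#'
#' @param stems a stem `data.frame` (see [readStemTable()]).
#' @param window the plot [Window].
#' @param species optional species to keep.
#' @param stage optional life stage to keep (`"sapling"`, `"juvenile"`,
#'   `"adult"`); requires `growthForm`.
#' @param growthForm growth form of the species (needed for staging; may be
#'   omitted when `stems` carries a `growth_form` column).
#' @param rules stage rule table, see [stageRules()].
#' @return A [PointPattern] with marks `species`, `dbh` and (when staged)
#'   `stage`.
#' @export
stemsToPattern <- function(stems, window = Window(), species = NULL,
                           stage = NULL, growthForm = NULL,
                           rules = stageRules()) {
  if (!is.null(species)) stems <- stems[stems$species %in% species, ]
  marks <- data.frame(species = stems$species, dbh = stems$dbh)
  if (!is.null(stage)) {
    gf <- if (!is.null(growthForm)) growthForm else stems$growth_form
    if (is.null(gf))
      stop("stage selection requires a growth form")
    st <- classifyStage(stems$dbh, gf, rules)
    keep <- st == stage
    stems <- stems[keep, ]
    marks <- cbind(marks[keep, , drop = FALSE], stage = st[keep])
  }
  PointPattern(stems$x, stems$y, window, marks)
}

#' Select focal species by per-stage abundance
#'
#' A species qualifies as focal when every life stage (sapling, juvenile,
#' adult) holds at least `minPerStage` individuals. The returned list is
#' deterministic and sorted.
#'
#' @param stems stem `data.frame` with columns `species`, `dbh` and
#'   `growth_form`.
#' @param rules stage rule table, see [stageRules()].
#' @param minPerStage minimum individuals required in each stage
#'   (default 40).
#' @return Sorted character vector of focal species (possibly empty).
#' @export
selectFocalSpecies <- function(stems, rules = stageRules(),
                               minPerStage = 40) {
  if (is.null(stems$growth_form))
    stop("stems must carry a 'growth_form' column")
  stage <- classifyStage(stems$dbh, stems$growth_form, rules)
  tab <- table(stems$species, factor(stage, levels = c("sapling", "juvenile",
                                                       "adult")))
  ok <- apply(tab >= minPerStage, 1, all)
  sort(rownames(tab)[ok])
}

#' Quadrat lattice of seedling plots
#'
#' The standard seedling-census layout: one 4-m^2 (2 x 2 m) seedling plot in
#' the north-west corner of each 10 x 10 m subplot. Quadrat ids run
#' row-major from the window origin; a 300 x 300 m window yields 900
#' quadrats.
#'
#' @param window the plot [Window].
#' @param spacing subplot side length (m), default 10.
#' @param plotSide seedling-plot side length (m), default 2.
#' @return A `data.frame` with columns `quadrat_id`, `x`, `y` (plot centre,
#'   m).
#' @export
quadratLattice <- function(window, spacing = 10, plotSide = 2) {
  nx <- floor((window@xMax - window@xMin) / spacing + 1e-9)
  ny <- floor((window@yMax - window@yMin) / spacing + 1e-9)
  ij <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  data.frame(
    quadrat_id = seq_len(nx * ny),
    x = window@xMin + ij$i * spacing + plotSide / 2,
    y = window@yMin + ij$j * spacing + spacing - plotSide / 2)
}

#' Read a seedling census with habitat covariates
#'
#' Reads a seedling table (`tag,quadrat_id,species,height_cm,alive_2005,
#' alive_2007,alive_2008,alive_2010`, flags 0/1) together with a habitat
#' table keyed by quadrat id (`quadrat_id,canopy_openness,topo_class`
#' with optional `altitude`). Validates that no seedling re-appears alive
#' after being recorded dead, that heights are positive, that quadrat ids
#' belong to the window's seedling lattice, and that habitat covariates are
#' in range. The five-year survival outcome (`alive_2005 & alive_2010`) is
#' attached; intermediate censuses are used for validation only. Seedlings
#' flagged in an optional `graduated_2010` column (crossed the 1 cm dbh
#' census threshold by the final census) are scored as survivors and
#' reported in the `graduated` column. Quadrats without a habitat row are
#' kept and flagged via `habitat_missing`.
#'
#' @param path seedling census CSV path.
#' @param habitatPath habitat covariate CSV path.
#' @param window the plot [Window] defining the quadrat lattice.
#' @return A list with components `seedlings` (records with `survival`,
#'   quadrat-centre coordinates and `habitat_missing` attached) and
#'   `habitat`.
#' @export
readSeedlingCensus <- function(path, habitatPath, window = Window()) {
  sdl <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("tag", "quadrat_id", "species", "height_cm", "alive_2005",
                "alive_2007", "alive_2008", "alive_2010")
  missing <- setdiff(required, names(sdl))
  if (length(missing))
    stop("seedling table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(is.na(sdl$height_cm) | sdl$height_cm <= 0))
    stop("seedling heights must be positive")
  alive <- as.matrix(sdl[, c("alive_2005", "alive_2007", "alive_2008",
                             "alive_2010")]) > 0
  revived <- apply(alive, 1, function(a) any(diff(a) > 0))
  if (any(revived))
    stop("seedling(s) recorded alive after death: tag ",
         paste(sdl$tag[revived], collapse = ", "))
  lattice <- quadratLattice(window)
  qidx <- match(sdl$quadrat_id, lattice$quadrat_id)
  if (anyNA(qidx))
    stop("unknown quadrat_id(s): ",
         paste(unique(sdl$quadrat_id[is.na(qidx)]), collapse = ", "))

  hab <- read.csv(habitatPath, stringsAsFactors = FALSE)
  if (!all(c("quadrat_id", "canopy_openness", "topo_class") %in% names(hab)))
    stop("habitat table must have columns quadrat_id, canopy_openness, topo_class")
  if (any(is.na(hab$canopy_openness) | hab$canopy_openness < 0 |
          hab$canopy_openness > 100))
    stop("canopy_openness must lie in [0, 100]")
  topoLevels <- c("ridge", "upper slope", "lower slope", "valley")
  if (!all(hab$topo_class %in% topoLevels))
    stop("topo_class must be one of: ", paste(topoLevels, collapse = ", "))
  if (anyDuplicated(hab$quadrat_id))
    stop("habitat table has duplicate quadrat_id(s)")

  graduated <- if (!is.null(sdl$graduated_2010)) sdl$graduated_2010 > 0
               else rep(FALSE, nrow(sdl))
  sdl$graduated <- graduated
  sdl$survival <- as.integer(alive[, 1] & (alive[, 4] | graduated))
  sdl$x <- lattice$x[qidx]
  sdl$y <- lattice$y[qidx]
  sdl$habitat_missing <- !(sdl$quadrat_id %in% hab$quadrat_id)
  list(seedlings = sdl, habitat = hab)
}
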