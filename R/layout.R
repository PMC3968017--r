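# Plate layout: which wells hold which sample, in which role, plus the
# sample-prep parameters needed for unit conversion.

#' Sample preparation parameters
#'
#' Describes one prepared sample (tissue extract or culture supernatant) as
#' it enters the plate, carrying everything needed to convert a raw per-well
#' activity (pmol/min) into a specific activity. All volume/mass conversions
#' use the 1 ml = 1 g convention.
#'
#' @param sample_id Sample label.
#' @param category `"tissue"` (specific activity per gram of tissue) or
#'   `"supernatant"` (volumetric activity per ml).
#' @param sample_mass Grams of tissue extracted (for supernatant, ml of
#'   culture supernatant, interpreted as grams).
#' @param buffer_volume ml of extraction buffer added (typically 2.5 volumes
#'   per gram of tissue; 0 for neat supernatant).
#' @param aliquot ml of prepared extract/supernatant pipetted into each assay
#'   well. Default 0.003 (3 µl).
#' @param dilution_factor Post-hoc dilution multiplier, >= 1: a sample
#'   diluted 1:9 before assay has `dilution_factor = 10`.
#' @param group Optional label tying together replicate preparations of the
#'   same biological source (defaults to `sample_id`).
#' @return An object of class `sample_spec`.
#' @examples
#' sample_spec("fish1", "tissue", sample_mass = 1, buffer_volume = 2.5)
#' @export
sample_spec <- function(sample_id,
                        category = c("tissue", "supernatant"),
                        sample_mass = 1,
                        buffer_volume = 0,
                        aliquot = 0.003,
                        dilution_factor = 1,
                        group = sample_id) {
  category <- match.arg(category)
  if (!is.finite(sample_mass) || sample_mass <= 0) {
    stop_domain("sample_mass must be > 0")
  }
  if (!is.finite(buffer_volume) || buffer_volume < 0) {
    stop_domain("buffer_volume must be >= 0")
  }
  if (!is.finite(aliquot) || aliquot <= 0 || aliquot > 0.1) {
    stop_domain("aliquot must lie in (0, 0.1] ml (well volume)")
  }
  if (!is.finite(dilution_factor) || dilution_factor < 1) {
    stop_domain("dilution_factor must be >= 1")
  }
  structure(
    list(sample_id = as.character(sample_id), category = category,
         sample_mass = sample_mass, buffer_volume = buffer_volume,
         aliquot = aliquot, dilution_factor = dilution_factor,
         group = as.character(group)),
    class = "sample_spec"
  )
}

#' Construct a plate layout
#'
#' Maps wells to samples and roles. Every assigned sample must have at least
#' one experimental well (with thiamine) and one control well (without);
#' the standard formats are 4+4 (12-sample plate) and 2+2 (24-sample plate).
#'
#' @param assignments Data frame with columns `well`, `sample_id`, `role`
#'   (`"experimental"` or `"control"`) and optionally `replicate` (filled in
#'   per sample/role if absent).
#' @param samples Named list of [sample_spec()] objects, one per sample
#'   referenced in `assignments`.
#' @return An object of class `plate_layout` with tibble `assignments` and
#'   list `samples`.
#' @export
plate_layout <- function(assignments, samples) {
  assignments <- tibble::as_tibble(assignments)
  need <- c("well", "sample_id", "role")
  if (!all(need %in% names(assignments))) {
    stop_layout(sprintf("assignments need columns %s",
                        paste(need, collapse = ", ")))
  }
  assignments$well <- normalize_well(assignments$well)
  assignments$sample_id <- as.character(assignments$sample_id)
  if (anyDuplicated(assignments$well)) {
    w <- assignments$well[duplicated(assignments$well)][[1]]
    stop_layout(sprintf("well %s assigned more than once", w))
  }
  if (!all(assignments$role %in% c("experimental", "control"))) {
    bad <- setdiff(unique(assignments$role), c("experimental", "control"))
    stop_layout(sprintf("unknown role '%s'", bad[[1]]))
  }
  if (!is.list(samples) || is.null(names(samples)) ||
      !all(vapply(samples, inherits, logical(1), "sample_spec"))) {
    stop_layout("samples must be a named list of sample_spec objects")
  }
  unknown <- setdiff(assignments$sample_id, names(samples))
  if (length(unknown) > 0) {
    stop_layout(sprintf("well %s assigned to unknown sample '%s'",
                        assignments$well[assignments$sample_id == unknown[[1]]][[1]],
                        unknown[[1]]))
  }
  for (sid in unique(assignments$sample_id)) {
    roles <- assignments$role[assignments$sample_id == sid]
    if (!any(roles == "experimental")) {
      stop_layout(sprintf("sample '%s' has no experimental wells", sid))
    }
    if (!any(roles == "control")) {
      stop_layout(sprintf("sample '%s' has no control wells", sid))
    }
  }
  if (!"replicate" %in% names(assignments)) {
    assignments <- dplyr::mutate(
      dplyr::group_by(assignments, .data$sample_id, .data$role),
      replicate = dplyr::row_number())
    assignments <- dplyr::ungroup(assignments)
  }
  ord <- order(assignments$sample_id, assignments$role, assignments$replicate)
  structure(
    list(assignments = assignments[ord, ],
         samples = samples[unique(assignments$sample_id)]),
    class = "plate_layout"
  )
}

#' @export
print.plate_layout <- function(x, ...) {
  n_exp <- sum(x$assignments$role == "experimental")
  n_ctrl <- sum(x$assignments$role == "control")
  cat(sprintf("<plate_layout> %d samples over %d wells (%d experimental + %d control)\n",
              length(x$samples), nrow(x$assignments), n_exp, n_ctrl))
  invisible(x)
}

#' Read a plate layout from a YAML config
#'
#' The config declares `samples` (a map of sample id to [sample_spec()]
#' fields; `aliquot` defaults to 0.003 ml and `dilution_factor` to 1) and
#' `wells` (a map of well address to `{sample: <id>, role: experimental|control}`).
#'
#' @param path Path to the YAML file.
#' @return A validated `plate_layout`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("samples:",
#'              "  S1: {category: supernatant}",
#'              "wells:",
#'              "  A1: {sample: S1, role: experimental}",
#'              "  B1: {sample: S1, role: control}"), f)
#' read_layout(f)
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop_layout(sprintf("file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$samples) || is.null(cfg$wells)) {
    stop_layout("layout config needs 'samples' and 'wells' sections")
  }
  samples <- lapply(names(cfg$samples), function(sid) {
    s <- cfg$samples[[sid]]
    do.call(sample_spec, c(list(sample_id = sid), s))
  })
  names(samples) <- names(cfg$samples)
  assignments <- do.call(rbind, lapply(names(cfg$wells), function(w) {
    a <- cfg$wells[[w]]
    if (is.null(a$sample) || is.null(a$role)) {
      stop_layout(sprintf("well %s needs 'sample' and 'role'", w))
    }
    data.frame(well = w, sample_id = a$sample, role = a$role,
               stringsAsFactors = FALSE)
  }))
  plate_layout(assignments, samples)
}
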