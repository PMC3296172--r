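# Strain -> species mapping with focal/outgroup designation.

#' Construct a species partition
#'
#' @param mapping data.frame with columns `strain_id`, `species`, `role`
#'   (`focal` or `outgroup`).
#' @param focal_species optional character vector; defaults to the species of
#'   strains with role `focal`.
#' @param outgroup_strains optional character vector; defaults to strains with
#'   role `outgroup`.
#' @return Object of class `species_partition`.
#' @export
species_partition <- function(mapping, focal_species = NULL,
                              outgroup_strains = NULL) {
  req <- c("strain_id", "species", "role")
  if (!all(req %in% names(mapping)))
    bd_stop("bd_format_error", "species map needs columns: %s",
            paste(req, collapse = ", "))
  if (nrow(mapping) == 0L)
    bd_stop("bd_format_error", "species map is empty")
  if (anyDuplicated(mapping$strain_id))
    bd_stop("bd_format_error", "duplicate strain_id in species map: %s",
            mapping$strain_id[duplicated(mapping$strain_id)][1L])
  if (any(!nzchar(mapping$species)))
    bd_stop("bd_format_error", "empty species label in species map")
  if (!all(mapping$role %in% c("focal", "outgroup")))
    bd_stop("bd_format_error", "role must be 'focal' or 'outgroup'")
  focal_species <- focal_species %||%
    unique(mapping$species[mapping$role == "focal"])
  outgroup_strains <- outgroup_strains %||%
    mapping$strain_id[mapping$role == "outgroup"]
  if (length(focal_species) == 0L)
    bd_stop("bd_validation_error", "no focal species in partition")
  focal_strains <- mapping$strain_id[mapping$species %in% focal_species]
  if (length(intersect(outgroup_strains, focal_strains)))
    bd_stop("bd_validation_error",
            "outgroup strains overlap focal species' strains")
  structure(list(mapping = mapping[, req], focal_species = focal_species,
                 outgroup_strains = outgroup_strains),
            class = "species_partition")
}

#' Read a strain-to-species map from TSV
#'
#' Expects tab-separated columns `strain_id`, `species`, `role`.
#'
#' @param path path to the TSV file.
#' @return A [species_partition()].
#' @export
read_species_map <- function(path) {
  if (!file.exists(path))
    bd_stop("bd_format_error", "species map not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#")
  species_partition(df)
}

#' Write a species partition to TSV
#' @param partition a `species_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_map <- function(partition, path) {
  utils::write.table(partition$mapping, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Species label of each strain (named vector), erroring on unmapped strains.
species_of <- function(partition, strains) {
  m <- partition$mapping
  idx <- match(strains, m$strain_id)
  if (anyNA(idx))
    bd_stop("bd_validation_error", "strain(s) absent from species map: %s",
            paste(strains[is.na(idx)], collapse = ", "))
  stats::setNames(m$species[idx], strains)
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf("<species_partition> %d strains, %d focal species, %d outgroup strains\n",
              nrow(x$mapping), length(x$focal_species),
              length(x$outgroup_strains)))
  invisible(x)
}
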