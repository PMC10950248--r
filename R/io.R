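# Serialization: YAML configuration round-trips, CSV column and result
# tables, JSON manifests.

matToList <- function(m) {
  list(rows = rownames(m), cols = colnames(m), values = as.vector(t(m)))
}
listToMat <- function(l) {
  matrix(as.numeric(l$values),
    nrow = length(l$rows), byrow = TRUE,
    dimnames = list(unlist(l$rows), unlist(l$cols))
  )
}

#' Read and write column configurations
#'
#' Configurations are stored as YAML; the connectivity matrices are
#' written with explicit row/column type names so a round trip restores
#' the exact configuration.
#'
#' @param config a configuration list (see [defaultColumnConfig()]).
#' @param path file path.
#' @return `readColumnConfig` returns the configuration list.
#' @export
writeColumnConfig <- function(config, path) {
  cfg <- config
  for (f in c("pBase", "wBar", "sigma")) {
    cfg$connectivity[[f]] <- matToList(config$connectivity[[f]])
  }
  cfg$connectivity$tauSyn <- as.list(config$connectivity$tauSyn)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeColumnConfig
#' @export
readColumnConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  required <- c("geometry", "types", "connectivity", "lgn", "background")
  miss <- setdiff(required, names(cfg))
  if (length(miss))
    stop("config is missing section(s): ", paste(miss, collapse = ", "))
  for (f in c("pBase", "wBar", "sigma")) {
    cfg$connectivity[[f]] <- listToMat(cfg$connectivity[[f]])
  }
  cfg$connectivity$delayRange <- as.integer(unlist(cfg$connectivity$delayRange))
  cfg$connectivity$tauSyn <- unlist(cfg$connectivity$tauSyn)
  cfg$geometry$layerDepths <- lapply(cfg$geometry$layerDepths, unlist)
  cfg
}

#' Write and read a column as CSV tables
#'
#' Writes `neurons.csv`, `recurrent.csv`, `lgn.csv`, `background.csv`,
#' `lgn_units.csv`, the YAML configuration and a JSON manifest (seed,
#' counts) into a directory; `readColumn` rebuilds the identical
#' [CorticalColumn-class] object.
#'
#' @param column a [CorticalColumn-class].
#' @param dir output directory (created if needed).
#' @return `readColumn` returns the column; `writeColumn` the directory,
#'   invisibly.
#' @export
writeColumn <- function(column, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f))
  fw(column@neurons, "neurons.csv")
  fw(column@recurrent, "recurrent.csv")
  fw(column@lgn, "lgn.csv")
  fw(data.frame(id = seq_along(column@background),
                weight = column@background), "background.csv")
  fw(column@lgnUnits, "lgn_units.csv")
  writeColumnConfig(column@config, file.path(dir, "config.yaml"))
  manifest <- list(
    seed = column@seed, nNeurons = nNeurons(column),
    nRecurrent = nrow(column@recurrent), nLGN = nrow(column@lgn)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname writeColumn
#' @export
readColumn <- function(dir) {
  fr <- function(f) {
    as.data.frame(data.table::fread(file.path(dir, f)))
  }
  cfg <- readColumnConfig(file.path(dir, "config.yaml"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  glif <- lapply(cfg$types, function(tc) do.call(GLIFParams, tc$glif))
  new("CorticalColumn",
    neurons = fr("neurons.csv"), recurrent = fr("recurrent.csv"),
    lgn = fr("lgn.csv"), background = fr("background.csv")$weight,
    lgnUnits = fr("lgn_units.csv"), glif = glif,
    geometry = cfg$geometry, config = cfg,
    seed = as.integer(manifest$seed)
  )
}

#' Export a spike raster as CSV
#'
#' @param sim a [FlowSimResult-class].
#' @param path CSV path; columns `trial`, `neuron_id`, `time_ms`.
#' @export
writeSpikeRaster <- function(sim, path) {
  spk <- spikeRaster(sim)
  data.table::fwrite(
    data.frame(
      trial = spk$trial, neuron_id = spk$neuron,
      time_ms = spk$step * sim@dt
    ),
    path
  )
  invisible(path)
}
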