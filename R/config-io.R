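#' Read a model configuration from YAML
#'
#' The file layout matches [write_avn_config()]: a `cells` mapping (one
#' record per cell label with fields `zone`, `k`, `a1`, `a2`, `mu1`, `mu2`,
#' `eps0`, `ct`), a `junctions` list (records with `from`, `to`, `d`,
#' `alpha`) and an `entry` mapping naming the stimulus entry points.
#'
#' @param path YAML file path.
#' @return a configuration list suitable for [build_topology()].
#' @export
read_avn_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$cells) || is.null(y$junctions))
    stop("configuration must contain 'cells' and 'junctions'")
  cells <- do.call(rbind, lapply(names(y$cells), function(lab) {
    r <- y$cells[[lab]]
    data.frame(label = lab, zone = r$zone, k = r$k, a1 = r$a1, a2 = r$a2,
               mu1 = r$mu1, mu2 = r$mu2, eps0 = r$eps0, ct = r$ct,
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- cells$label
  jn <- do.call(rbind, lapply(y$junctions, function(r) {
    data.frame(from = r$from, to = r$to, d = r$d, alpha = r$alpha,
               stringsAsFactors = FALSE)
  }))
  entry <- y$entry
  if (is.null(entry))
    entry <- list(antero = "AM1", retro = "HB1", af = "AM*")
  list(cells = cells, junctions = jn, entry = entry)
}

#' Write a model configuration to YAML
#'
#' @param config configuration list (`cells`, `junctions`, `entry`).
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_avn_config <- function(config, path) {
  cells <- config$cells
  cl <- lapply(seq_len(nrow(cells)), function(i) {
    list(zone = cells$zone[i], k = cells$k[i], a1 = cells$a1[i],
         a2 = cells$a2[i], mu1 = cells$mu1[i], mu2 = cells$mu2[i],
         eps0 = cells$eps0[i], ct = cells$ct[i])
  })
  names(cl) <- cells$label
  jn <- config$junctions
  jl <- lapply(seq_len(nrow(jn)), function(i) {
    list(from = jn$from[i], to = jn$to[i], d = jn$d[i], alpha = jn$alpha[i])
  })
  yaml::write_yaml(list(cells = cl, junctions = jl, entry = config$entry),
                   path, precision = 12)
  invisible(path)
}

#' Path of the shipped default configuration file
#'
#' The YAML copy of [default_config()] installed with the package, for use
#' from the command line or as a template for custom configurations.
#'
#' @return file path.
#' @export
default_config_path <- function() {
  system.file("extdata", "rabbit_default.yaml", package = "avnsim",
              mustWork = TRUE)
}
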