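# plain-text readers and writers for every pipeline input/output

#' Read and write tidy trace CSV
#'
#' Long format with columns `time_s, roi_id, side, value`.
#'
#' @param traces a [bilateral_traces()] object.
#' @param path CSV file path.
#' @return `read_traces_csv` returns a [bilateral_traces()];
#'   `write_traces_csv` returns `path` invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "bilateral_traces"))
  utils::write.csv(traces$data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  t_one <- sort(unique(d$time_s))
  fps <- 1 / stats::median(diff(t_one))
  bilateral_traces(tibble::as_tibble(d), fps = fps,
                   duration = max(t_one) + 1 / fps)
}

#' Read and write midline CSV
#'
#' Columns `fish_id, point_index, x, y`; one or many fish per file.
#'
#' @param axes a [body_axis()] or list of them.
#' @param path CSV file path.
#' @return `read_midlines_csv` returns a named list of
#'   [body_axis()] objects.
#' @export
write_midlines_csv <- function(axes, path) {
  if (inherits(axes, "body_axis")) axes <- list(axes)
  rows <- lapply(seq_along(axes), function(i) {
    ax <- axes[[i]]
    id <- if (!is.na(ax$fish_id)) ax$fish_id else sprintf("fish%03d", i)
    data.frame(fish_id = id, point_index = seq_along(ax$x),
               x = ax$x, y = ax$y)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_midlines_csv
#' @export
read_midlines_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(d, d$fish_id), function(f) {
    f <- f[order(f$point_index), ]
    body_axis(f$x, f$y, fish_id = f$fish_id[1])
  })
  out
}

#' Read and write cohort count CSV
#'
#' Columns `group, variant_alleles, total_alleles`.
#'
#' @param tab a [cohort_table()].
#' @param path CSV file path.
#' @export
write_cohort_csv <- function(tab, path) {
  utils::write.csv(tab[c("group", "variant_alleles", "total_alleles")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort_table(d$group, d$variant_alleles, d$total_alleles)
}

#' Read and write multichannel sEMG CSV with a YAML sidecar
#'
#' Long CSV (`time_s, channel, value`) plus `<path>.yaml` holding
#' `fs`, `gain` and `posture`.
#'
#' @param rec a [semg_recording()].
#' @param path CSV file path; the sidecar is `<path>.yaml`.
#' @export
write_semg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "semg_recording"))
  n <- length(rec$channels[[1]])
  t_grid <- (seq_len(n) - 1L) / rec$fs
  d <- do.call(rbind, lapply(names(rec$channels), function(nm)
    data.frame(time_s = t_grid, channel = nm,
               value = rec$channels[[nm]])))
  utils::write.csv(d, path, row.names = FALSE)
  yaml::write_yaml(list(fs = rec$fs, gain = rec$gain,
                        posture = rec$posture),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_semg_csv
#' @export
read_semg_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  chans <- lapply(split(d, d$channel), function(ch)
    ch$value[order(ch$time_s)])
  semg_recording(chans, fs = meta$fs, gain = meta$gain,
                 posture = meta$posture)
}

#' Read and write uptake plate CSV
#'
#' Columns `well, genotype, nmol, time_min, protein_mg, replicate`.
#'
#' @param plate an [uptake_plate()].
#' @param path CSV file path.
#' @export
write_uptake_csv <- function(plate, path) {
  utils::write.csv(
    plate[c("well", "genotype", "nmol", "time_min", "protein_mg",
            "replicate")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_uptake_csv
#' @export
read_uptake_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  uptake_plate(d$well, d$genotype, d$nmol, d$time_min, d$protein_mg,
               d$replicate)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Reading is
#' delegated to [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of set descriptions.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a query gene list (one identifier per line)
#'
#' @param path text file path; blank lines and leading/trailing
#'   whitespace are dropped.
#' @return character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}
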