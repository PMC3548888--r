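# Binary per-base MUL track format. One file per sequence: position i
# lives at byte offset i*width (little-endian for width 2), so the file
# size is exactly sequence length x width. A YAML sidecar per file
# carries the metadata needed to interpret and validate the track.

sidecar_path <- function(path) paste0(path, ".yml")

#' Write a MUL array to a binary track file
#'
#' Encodes one value per base, using one byte per position (values up to
#' 255) or two little-endian bytes (values up to 65535). A text sidecar
#' `<path>.yml` records the sequence name, length, read-length range,
#' mode, value width and tool version so the track is self-describing.
#'
#' @param array A [mul_array()].
#' @param path Output file path (conventionally
#'   `<seq_name>.mul<width>` inside a track directory).
#' @param value_width 1 (default) or 2 bytes per position.
#' @param overwrite Overwrite an existing file? Default `FALSE`.
#' @param genome_build Optional build label stored in the sidecar.
#' @return `path`, invisibly.
#' @seealso [read_mul_file()], [mul_file_set()]
#' @export
write_mul_file <- function(array, path, value_width = 1L, overwrite = FALSE,
                           genome_build = NA_character_) {
  stopifnot(inherits(array, "MULArray"), value_width %in% c(1L, 2L))
  limit <- if (value_width == 1L) 255L else 65535L
  if (array$kmax > limit || any(array$values > limit)) {
    stop("values exceed ", value_width, "-byte range (max ", limit, ")")
  }
  if (file.exists(path) && !overwrite) {
    stop("file exists (use overwrite = TRUE): ", path)
  }
  v <- array$values
  bytes <- if (value_width == 1L) {
    as.raw(v)
  } else {
    as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(bytes, con)
  meta <- list(seq_name = array$seq_name, length = length(v),
               kmin = array$kmin, kmax = array$kmax, mode = array$mode,
               value_width = as.integer(value_width),
               genome_build = genome_build,
               tool = paste0("mulmap ",
                             as.character(utils::packageVersion("mulmap"))))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a binary MUL track file
#'
#' Inverse of [write_mul_file()]: values and metadata round-trip
#' exactly. The file size is validated against the sidecar.
#'
#' @param path Path to the binary track (the sidecar `<path>.yml` must
#'   exist next to it).
#' @return A [mul_array()].
#' @export
read_mul_file <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing sidecar ", sc,
         " (re-write the track with write_mul_file to regenerate it)")
  }
  meta <- yaml::read_yaml(sc)
  width <- meta$value_width
  expected <- meta$length * width
  if (file.info(path)$size != expected) {
    stop("file size ", file.info(path)$size, " does not match sidecar (",
         meta$length, " positions x ", width, " byte(s) = ", expected, ")")
  }
  bytes <- readBin(path, "raw", n = expected)
  values <- if (width == 1L) {
    as.integer(bytes)
  } else {
    b <- as.integer(bytes)
    b[c(TRUE, FALSE)] + 256L * b[c(FALSE, TRUE)]
  }
  mul_array(meta$seq_name, values, meta$kmin, meta$kmax, meta$mode)
}

#' Open a directory of MUL track files as a queryable set
#'
#' Scans `directory` for `*.mul1`/`*.mul2` files with sidecars, one per
#' sequence. Tracks are loaded lazily on first query and cached.
#'
#' @param directory Path containing track files written by
#'   [write_mul_files()] or [write_mul_file()].
#' @return An object of class `MULFileSet`.
#' @export
mul_file_set <- function(directory) {
  files <- list.files(directory, pattern = "\\.mul[12]$", full.names = TRUE)
  if (!length(files)) stop("no .mul1/.mul2 files found in ", directory)
  seq_names <- unsanitize_name(sub("\\.mul[12]$", "", basename(files)))
  structure(list(directory = directory,
                 files = setNames(files, seq_names),
                 cache = new.env(parent = emptyenv())),
            class = "MULFileSet")
}

#' Write a list of MUL arrays as a track set
#'
#' @param arrays A list of [mul_array()]s (e.g. from
#'   [compute_bisulfite_mul()]).
#' @param directory Output directory (created if needed). Files are
#'   named `<sanitized seq_name>.mul<width>`.
#' @inheritParams write_mul_file
#' @return A [mul_file_set()] over `directory`.
#' @export
write_mul_files <- function(arrays, directory, value_width = 1L,
                            overwrite = FALSE, genome_build = NA_character_) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (inherits(arrays, "MULArray")) arrays <- list(arrays)
  for (a in arrays) {
    path <- file.path(directory,
                      paste0(sanitize_name(a$seq_name), ".mul", value_width))
    write_mul_file(a, path, value_width = value_width, overwrite = overwrite,
                   genome_build = genome_build)
  }
  mul_file_set(directory)
}

#' @export
print.MULFileSet <- function(x, ...) {
  cat("MULFileSet:", length(x$files), "track(s) in", x$directory, "\n")
  invisible(x)
}

set_array <- function(files, seq_name) {
  if (!seq_name %in% names(files$files)) {
    stop("no MUL track for sequence ", sQuote(seq_name))
  }
  key <- sanitize_name(seq_name)
  if (is.null(files$cache[[key]])) {
    files$cache[[key]] <- read_mul_file(files$files[[seq_name]])
  }
  files$cache[[key]]
}

#' Query MUL values and uniqueness over a region
#'
#' A position is uniquely mappable at `read_length` iff its stored MUL
#' value is nonzero and no larger than `read_length`. Read lengths above
#' the stored `kmax` are capped to `kmax` with a warning, since a stored
#' 0 cannot distinguish "needs more than kmax" from "never unique".
#'
#' @param files A [mul_file_set()].
#' @param seq_name Sequence to query.
#' @param start,end 0-based half-open region bounds.
#' @param read_length Read length of interest (at least the stored
#'   `kmin`).
#' @return A data frame with `position` (0-based), `mul` and `unique`.
#' @export
query_region <- function(files, seq_name, start, end, read_length) {
  stopifnot(inherits(files, "MULFileSet"))
  arr <- set_array(files, seq_name)
  n <- length(arr$values)
  if (!(start >= 0 && start < end && end <= n)) {
    stop("region [", start, ", ", end, ") out of bounds for ", seq_name,
         " of length ", n, " (need 0 <= start < end <= ", n, ")")
  }
  if (read_length < arr$kmin) {
    stop("read_length ", read_length, " below stored kmin ", arr$kmin)
  }
  if (read_length > arr$kmax) {
    warning("read_length ", read_length, " above stored kmax ", arr$kmax,
            "; capped to ", arr$kmax)
    read_length <- arr$kmax
  }
  v <- arr$values[(start + 1L):end]
  data.frame(position = start:(end - 1L), mul = v,
             unique = v > 0L & v <= read_length)
}

#' Proportion of uniquely mappable positions in regions
#'
#' For each region, the fraction of positions whose MUL value is nonzero
#' and at most `read_length`. The denominator counts either only
#' positions where a full read of `read_length` fits inside the sequence
#' (`"fitting"`, default — matches how reads are generated) or every
#' position of the region (`"all"`). A pooled estimate over all regions
#' (sum of numerators over sum of denominators) is returned alongside.
#'
#' @param files A [mul_file_set()].
#' @param regions Data frame with columns `seq_name`, `start`, `end`
#'   (0-based half-open), e.g. from [read_bed_regions()].
#' @param read_length Read length of interest.
#' @param denominator `"fitting"` or `"all"`.
#' @return A list with `per_region` (the input regions plus
#'   `n_unique`, `n_positions`, `proportion`) and `pooled`.
#' @export
proportion_unique <- function(files, regions, read_length,
                              denominator = c("fitting", "all")) {
  stopifnot(inherits(files, "MULFileSet"))
  denominator <- match.arg(denominator)
  regions <- as.data.frame(regions)
  if (nrow(regions) == 0L) stop("empty region list")
  num <- den <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    arr <- set_array(files, regions$seq_name[i])
    n <- length(arr$values)
    start <- regions$start[i]
    end <- regions$end[i]
    if (!(start >= 0 && start < end && end <= n)) {
      stop("region [", start, ", ", end, ") out of bounds for ",
           regions$seq_name[i])
    }
    rl <- min(read_length, arr$kmax)
    if (read_length < arr$kmin) {
      stop("read_length ", read_length, " below stored kmin ", arr$kmin)
    }
    d_end <- if (denominator == "fitting") {
      min(end, n - rl + 1L)  # last start hosting a full read, clipped
    } else {
      end
    }
    den[i] <- max(0L, d_end - start)
    if (den[i] > 0L) {
      v <- arr$values[(start + 1L):d_end]
      num[i] <- sum(v > 0L & v <= rl)
    }
  }
  regions$n_unique <- num
  regions$n_positions <- den
  regions$proportion <- ifelse(den > 0L, num / den, 0)
  list(per_region = regions,
       pooled = if (sum(den) > 0L) sum(num) / sum(den) else 0)
}

#' Read a BED file as a region table
#'
#' Minimal BED3+ reader: the first three columns (chrom, 0-based start,
#' end) become `seq_name`, `start`, `end`; a fourth column, if present,
#' becomes `name`.
#'
#' @param path Path to a BED file.
#' @return A data frame usable as `regions` in [proportion_unique()].
#' @export
read_bed_regions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- data.frame(
    seq_name = vapply(fields, `[[`, "", 1L),
    start = as.integer(vapply(fields, `[[`, "", 2L)),
    end = as.integer(vapply(fields, `[[`, "", 3L))
  )
  if (all(lengths(fields) >= 4L)) {
    out$name <- vapply(fields, `[[`, "", 4L)
  }
  out
}
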