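#' Tile chromosomes into (sliding) windows
#'
#' Windows are 0-based half-open `[start, end)`, start at 0, advance by `step`
#' (default = `size`, i.e. non-overlapping), and a final partial window is
#' included whenever it covers at least one bp. With `step = size` the windows
#' tile `[0, length)` with no gaps.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#' @param size window size in bp (default 100 kb)
#' @param step step between window starts, `1 <= step <= size`
#' @return a tibble with columns `chrom`, `start`, `end`
#' @export
make_windows <- function(chrom_lengths, size = 100000, step = size) {
  stopifnot(size >= 1, step >= 1, step <= size)
  if (is.null(names(chrom_lengths))) {
    abort("chrom_lengths must be named by chromosome")
  }
  if (any(chrom_lengths <= 0)) abort("chromosome lengths must be positive")
  purrr::map_dfr(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = step)
    tibble(chrom = ch, start = as.numeric(starts),
           end = pmin(starts + size, len))
  })
}

# 1-based site positions -> window row index (NA when outside all windows);
# windows are assumed non-overlapping when this helper is used
assign_windows <- function(chrom, pos, windows) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    w <- which(windows$chrom == ch)
    if (length(w) == 0L) next
    sel <- which(chrom == ch)
    # 1-based pos p lies in [start, end) iff start < p <= end
    j <- findInterval(pos[sel] - 1L, windows$start[w])
    ok <- j >= 1L & (pos[sel] - 1L) < windows$end[w][pmax(j, 1L)]
    idx[sel[ok]] <- w[j[ok]]
  }
  idx
}

#' Read gene models from a GFF3 file
#'
#' Keeps `gene` features; coordinates stay 1-based inclusive as in GFF3.
#' Gene identifiers come from the `ID=` (or `Name=`) attribute, falling back
#' to `gene_<n>`.
#'
#' @param path GFF3 file
#' @return a tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' @export
read_gff <- function(path) {
  g <- ape::read.gff(path)
  g <- g[g$type == "gene", , drop = FALSE]
  attr_id <- function(a) {
    id <- sub(".*(?:^|;)ID=([^;]+).*", "\\1", a)
    nm <- sub(".*(?:^|;)Name=([^;]+).*", "\\1", a)
    out <- ifelse(id != a, id, ifelse(nm != a, nm, NA_character_))
    out
  }
  ids <- attr_id(as.character(g$attributes))
  ids[is.na(ids)] <- paste0("gene_", which(is.na(ids)))
  tibble(gene_id = ids, chrom = as.character(g$seqid),
         start = as.integer(g$start), end = as.integer(g$end),
         strand = as.character(g$strand)) |>
    arrange(.data$chrom, .data$start)
}
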