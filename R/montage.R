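#' Resolve channel names to idealized 10-20 scalp coordinates
#'
#' Looks channel names up (case-insensitively) in the packaged 10-20 /
#' 10-10 coordinate table (`inst/extdata/montage_1020.tsv`): unit-sphere
#' positions with x toward the right ear, y toward the nasion, z through
#' the vertex. Unknown names are returned with `resolved = FALSE` and NA
#' coordinates rather than failing, so a montage is always obtained.
#'
#' @param channel_names Character vector of electrode names.
#' @return A tibble of class `montage` with columns `channel`, `x`,
#'   `y`, `z`, `resolved`.
#' @examples
#' standard_1020_montage(c("F3", "F4", "Cz", "XX9"))
#' @export
standard_1020_montage <- function(channel_names) {
  tbl <- montage_table()
  idx <- match(toupper(channel_names), toupper(tbl$channel))
  out <- tibble::tibble(
    channel = as.character(channel_names),
    x = tbl$x[idx], y = tbl$y[idx], z = tbl$z[idx],
    resolved = !is.na(idx)
  )
  if (any(!out$resolved)) {
    warn(paste0("Unresolved electrode names: ",
                paste(out$channel[!out$resolved], collapse = ", ")))
  }
  class(out) <- c("montage", class(out))
  out
}

montage_table <- function() {
  path <- system.file("extdata", "montage_1020.tsv",
                      package = "emoselect", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, sep = "\t"))
}
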