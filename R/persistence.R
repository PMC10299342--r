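#' Fluorescence-persistence percentages per group and timepoint
#'
#' Summarizes an animal presence/absence table into the fraction of animals
#' with detectable fluorescence at the injection site, reported as integer
#' percentages (rounded half away from zero, so 14/15 gives 93%).
#'
#' @param table A presence table from [read_presence_table()] (data.frame
#'   with `group`, `timepoint`, `animal`, logical `fluorescence_present`).
#' @return data.frame `group, timepoint, n_total, n_positive, percent`, one
#'   row per observed (group, timepoint) cell, ordered by group then
#'   timepoint. Empty cells are excluded with a warning.
#' @examples
#' tab <- data.frame(group = "C", timepoint = "day1", animal = 1:10,
#'                   fluorescence_present = c(rep(TRUE, 9), FALSE))
#' persistence_percentages(tab)  # 90%
#' @export
persistence_percentages <- function(table) {
  need <- c("group", "timepoint", "fluorescence_present")
  if (!all(need %in% names(table)))
    fail_input("presence table must have columns %s",
               paste(need, collapse = ", "))
  key <- interaction(table$group, table$timepoint, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- table[key == k, ]
    if (!nrow(sub)) {
      warning(sprintf("empty (group, timepoint) cell %s excluded", k),
              call. = FALSE)
      return(NULL)
    }
    data.frame(group = sub$group[1], timepoint = sub$timepoint[1],
               n_total = nrow(sub),
               n_positive = sum(sub$fluorescence_present),
               percent = as.integer(round_half_up(
                 100 * sum(sub$fluorescence_present) / nrow(sub))))
  })
  out <- do.call(rbind, rows)
  out[order(out$group, out$timepoint), , drop = FALSE]
}
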