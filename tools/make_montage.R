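# Build the idealized 10-20/10-10 unit-sphere coordinate table.
# Rows: constant antero-posterior polar angle from the vertex (front
# positive, 18 deg steps of the nasion-inion arc). Lateral positions:
# great-circle interpolation from the row's midline point toward the
# ear point (+-x), 18 deg steps (odd numbers left, even right).
rows <- c(FP = 72, AF = 54, F = 36, FC = 18, C = 0, CP = -18,
          P = -36, PO = -54, O = -72, CB = -81)
# name aliases living on other rows' arcs
alias_row <- c(T = "C", FT = "FC", TP = "CP")

lat_t <- function(num) {
  # electrode number -> fraction of the quarter arc toward the ear
  rank <- ceiling(num / 2)
  0.2 * rank
}

mk <- function(row_key, num) {
  a <- rows[[row_key]] * pi / 180
  M <- c(0, sin(a), cos(a))                      # row midline point
  if (num == 0) return(M)
  E <- c(if (num %% 2 == 1) -1 else 1, 0, 0)     # ear point (odd = left)
  t <- lat_t(num) * pi / 2
  M * cos(t) + E * sin(t)
}

names_list <- list()
add <- function(name, row_key, num) {
  names_list[[name]] <<- mk(row_key, num)
}
for (rk in names(rows)) {
  nums <- if (rk %in% c("FP", "O")) c(0, 1, 2)
  else if (rk == "AF") c(0, 3, 4, 7, 8)
  else if (rk == "CB") c(1, 2)
  else if (rk == "PO") c(0, 3, 4, 5, 6, 7, 8)
  else c(0, 1, 2, 3, 4, 5, 6)
  for (n in nums) {
    suffix <- if (n == 0) "z" else as.character(n)
    add(paste0(substr(rk, 1, 1), substr(tolower(rk), 2, 2), suffix), rk, n)
  }
}
# fix capitalisation quirks and aliased temporal names
proper <- function(rk, n) {
  base <- switch(rk, FP = "Fp", AF = "AF", F = "F", FC = "FC", C = "C",
                 CP = "CP", P = "P", PO = "PO", O = "O", CB = "CB")
  paste0(base, if (n == 0) "z" else n)
}
names_list <- list()
for (rk in names(rows)) {
  nums <- if (rk %in% c("FP", "O")) c(0, 1, 2)
  else if (rk == "AF") c(0, 3, 4, 7, 8)
  else if (rk == "CB") c(1, 2)
  else if (rk %in% c("F", "P")) c(0:8)   # F7/F8, P7/P8 are true row members
  else c(0, 1, 2, 3, 4, 5, 6)            # lateral-most are T/FT/TP aliases
  for (n in nums) names_list[[proper(rk, n)]] <- mk(rk, n)
}
# PO row also has 5/6/7/8 in 62-channel caps
for (n in 5:8) names_list[[paste0("PO", n)]] <- mk("PO", n)
# temporal aliases: T7/T8 = C row lateral rank 4, etc.
names_list[["T7"]] <- mk("C", 7); names_list[["T8"]] <- mk("C", 8)
names_list[["FT7"]] <- mk("FC", 7); names_list[["FT8"]] <- mk("FC", 8)
names_list[["TP7"]] <- mk("CP", 7); names_list[["TP8"]] <- mk("CP", 8)
names_list[["T3"]] <- mk("C", 7); names_list[["T4"]] <- mk("C", 8)
names_list[["T5"]] <- mk("P", 7); names_list[["T6"]] <- mk("P", 8)

tab <- data.frame(
  channel = names(names_list),
  x = round(vapply(names_list, `[`, 0, 1), 6),
  y = round(vapply(names_list, `[`, 0, 2), 6),
  z = round(vapply(names_list, `[`, 0, 3), 6)
)
tab <- tab[!duplicated(tab$channel), ]
write.table(tab, "inst/extdata/montage_1020.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat(nrow(tab), "electrodes written\n")
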