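## Fixtures built in code.

## hand-built lineage tree: founder divides PP at 34; daughter c002 divides
## PN at 37; all times hpf
makeSmallTree <- function(cloneId = "cl1", condition = "control") {
  nodes <- data.frame(
    id = c("c001", "c002", "c003", "c004", "c005"),
    parent = c(NA, "c001", "c001", "c002", "c002"),
    birth = c(32, 34, 34, 37, 37),
    divTime = c(34, 37, NA, NA, NA),
    mode = c("PP", "PN", NA, NA, NA),
    fate = c("P", "P", "P", "P", "N"))
  new("LineageTree", nodes = nodes, founderId = "c001", cloneId = cloneId,
      condition = condition)
}

## two-cell clone at t0 with chosen division times (NA = never divides)
makeSisterTree <- function(t1, t2, modes = c("PN", "PN"), cloneId = "s1") {
  nodes <- data.frame(
    id = c("c001", "c002", "c003"),
    parent = c(NA, "c001", "c001"),
    birth = c(30, 31, 31),
    divTime = c(31, t1, t2),
    mode = c("PP", ifelse(is.na(t1), NA, modes[1]),
             ifelse(is.na(t2), NA, modes[2])),
    fate = c("P", "P", "P"))
  kid <- function(par, m, td) {
    if (is.na(td)) return(NULL)
    f <- switch(m, PP = c("P", "P"), PN = c("P", "N"), NN = c("N", "N"))
    data.frame(id = paste0(par, c("a", "b")), parent = par, birth = td,
               divTime = NA_real_, mode = NA_character_, fate = f)
  }
  nodes <- rbind(nodes, kid("c002", modes[1], t1), kid("c003", modes[2], t2))
  new("LineageTree", nodes = nodes, founderId = "c001", cloneId = cloneId,
      condition = "control")
}

## minimal valid cell table
makeCellTable <- function(n = 3, time = 32) {
  m <- max(n, 1L)
  tb <- data.frame(cell_id = sprintf("x%02d", seq_len(m)), time_hpf = time,
                   x_um = 50, y_um = 5 * seq_len(m), z_um = 5,
                   r_mean = 0.1, g_mean = 0.8, b_mean = 0.1,
                   apical_contact = TRUE, embryo_id = "e01",
                   boundary_id = "b1")
  tb[seq_len(n), , drop = FALSE]
}
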