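# Shared fixture builders. Everything is generated in code; no data files.

# unit square extent (side km), lower-left at (x0, y0)
square_extent <- function(side = 10, x0 = 0, y0 = 0, label = "NBZ") {
  karst_extent(list(rbind(c(x0, y0), c(x0 + side, y0),
                          c(x0 + side, y0 + side), c(x0, y0 + side))),
               label, 0)
}

# records data.frame from parallel vectors
rec_df <- function(species, cell, subcell = NULL, x = NULL, y = NULL) {
  df <- data.frame(accepted_name = species, cell = cell,
                   stringsAsFactors = FALSE)
  if (!is.null(subcell)) df$subcell <- subcell
  if (!is.null(x)) { df$x <- x; df$decimal_longitude <- x }
  if (!is.null(y)) { df$y <- y; df$decimal_latitude <- y }
  df
}

# independent oracle: closed-form expectation of the random accumulation
# curve, E[S(n)] = sum_s (1 - C(N - m_s, n)/C(N, n))
hyper_expected_richness <- function(comm, n) {
  m <- colSums(comm > 0)
  N <- nrow(comm)
  vapply(n, function(k) sum(1 - exp(lchoose(N - m, k) - lchoose(N, k))),
         numeric(1))
}

# random occurrence layout over a c x c cell grid with `nsp` species
random_layout <- function(nsp = 30, ncell = 16, nrec = 300) {
  rec_df(sprintf("sp%03d", sample.int(nsp, nrec, replace = TRUE)),
         sprintf("c%02d", sample.int(ncell, nrec, replace = TRUE)))
}

# the 20-record keyword/proximity fixture with a hand-enumerated outcome.
# Karst polygon: square [0,10]x[0,10]. Carbonate anchors at (5,5), (20,20).
# Hand enumeration (rules: carbonate always retained; cave retained iff
# within 1 km of a carbonate record or of the polygon; doline retained iff
# inside the polygon):
#   r01 calcario  (5,5)    carbonate -> retained (anchor)
#   r02 Limestone (20,20)  carbonate -> retained (anchor, case-folded)
#   r03 calcário  (2,2)    carbonate -> retained (accent variant)
#   r04 dolomite  (40,40)  carbonate -> retained (unconditional even if far)
#   r05 gruta     (5.5,5)  cave      -> retained (0.5 km from r01)
#   r06 gruta     (20,21.4) cave     -> excluded (1.4 km from r02, outside)
#   r07 caverna   (10.5,5) cave      -> retained (0.5 km from polygon edge)
#   r08 cave      (30,30)  cave      -> excluded (far from all anchors)
#   r09 caverna   (19.5,20) cave     -> retained (0.5 km from r02)
#   r10 dolina    (3,3)    doline    -> retained (inside polygon)
#   r11 doline    (12,5)   doline    -> excluded (outside polygon)
#   r12 dolina    (20,20.2) doline   -> excluded (outside polygon, anchors
#                                       irrelevant to the doline rule)
#   r13 "gruta calcária" (50,50) carbonate (strongest class) -> retained
#   r14 neutral   (5,5)    no keyword -> not matched
#   r15 neutral   (0,0)    no keyword -> not matched
#   r16 karst     (7,7)    carbonate -> retained
#   r17 CAVE      (7.6,7)  cave      -> retained (inside polygon, dist 0)
#   r18 caliza    (60,60)  carbonate -> retained
#   r19 gruta     (60,60.5) cave     -> retained (0.5 km from r18)
#   r20 doline    (60,60)  doline    -> excluded (outside polygon)
validation_fixture <- function() {
  notes <- c("solo calcario raso", "Limestone outcrop", "solo calcário",
             "dolomite ridge", "entrada da gruta", "gruta seca",
             "boca da caverna", "cave entrance", "perto da caverna",
             "borda de dolina", "doline field", "dolina rasa",
             "gruta calcária", "floresta de terra firme", "campo sujo",
             "karst tower", "CAVE mouth", "caliza blanca", "gruta humeda",
             "doline dry")
  x <- c(5, 20, 2, 40, 5.5, 20, 10.5, 30, 19.5, 3, 12, 20, 50, 5, 0, 7,
         7.6, 60, 60, 60)
  y <- c(5, 20, 2, 40, 5, 21.4, 5, 30, 20, 3, 5, 20.2, 50, 5, 0, 7, 7,
         60, 60.5, 60)
  data.frame(record_id = sprintf("r%02d", 1:20), habitat_notes = notes,
             x = x, y = y, stringsAsFactors = FALSE)
}

validation_expected_retained <- c("r01", "r02", "r03", "r04", "r05", "r07",
                                  "r09", "r10", "r13", "r16", "r17", "r18",
                                  "r19")

# tiny landscape spec for fast generator tests
small_spec <- function(...) {
  args <- utils::modifyList(list(width_km = 300, height_km = 300,
                                 n_species = 60, n_records = 1500,
                                 seed = 11L), list(...))
  do.call(landscape_spec, args)
}
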