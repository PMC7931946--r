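# Shared fixtures, memoized so expensive fits run once per test session.

.fx <- new.env(parent = emptyenv())

fixture <- function(key, make) {
  if (is.null(.fx[[key]])) assign(key, make(), envir = .fx)
  get(key, envir = .fx)
}

smallSpec <- function() {
  syntheticSpec(nTargets = 4L, nFamilies = 2L, activesPerChemotype = 10L,
                decoyCount = 20L, seed = 17L)
}

smallGen <- function() fixture("smallGen", function() {
  generateReferenceDb(smallSpec())
})

smallModel <- function() fixture("smallModel", function() {
  suppressMessages(fitOTSA(smallGen()$db))
})

# the default study conditions: used by the acceptance and synthetic tests
defaultRun <- function() fixture("defaultRun", function() {
  t0 <- Sys.time()
  g <- generateReferenceDb(syntheticSpec())
  q <- generateQuerySet(g$truth, g$db)
  model <- suppressMessages(fitOTSA(g$db))
  pred <- predictTargets(model, q$queries)
  metrics <- evaluateRecovery(pred, q$expected)
  list(g = g, q = q, model = model, pred = pred, metrics = metrics,
       elapsed = as.numeric(Sys.time() - t0, units = "secs"))
})

# write a small activity table to a temp TSV and return the path
writeActivityTSV <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("mol_id\tsmiles\ttarget_id\tlabel",
               vapply(rows, paste, character(1), collapse = "\t")), path)
  path
}
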