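# Replicated experiment batches shared by the acceptance-level tests.
# 50 effective replicates is the reduced desk profile of the study's
# 200-replicate design; batches are computed once per test run.
.batchCache <- new.env(parent = emptyenv())

experimentBatch <- function(which) {
  if (!is.null(.batchCache[[which]])) return(.batchCache[[which]])
  val <- switch(which,
    # defaults: h2 = 0.30, 0.1 cM, sires + last-generation males genotyped
    defaults = runExperiment(simConfig(), nReplicates = 50, baseSeed = 1000),
    # low heritability, otherwise defaults
    lowH2 = runExperiment(simConfig(h2 = 0.03), nReplicates = 50,
                          baseSeed = 2000),
    # wide marker spacing (2 cM) for the density trend
    wide = runExperiment(simConfig(spacing = 0.02), nReplicates = 15,
                         baseSeed = 3000),
    # random parent choice instead of truncation selection
    noSelection = runExperiment(simConfig(selection = FALSE),
                                nReplicates = 8, baseSeed = 4000),
    stop("unknown batch"))
  .batchCache[[which]] <- val
  val
}
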