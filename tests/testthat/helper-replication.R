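# Full-protocol replication shared by the acceptance tests: trained once and
# cached for the session (the classifier and the 12-participant replication
# together take several minutes).

full_replication <- function() {
  fixture("full_replication", function() {
    cfg <- sim_config(seed = 42L)
    cls <- train_replication_classifier(cfg)
    hold <- evaluate_classifier_holdout(cls$model, cfg, n_test = 100L)
    rep <- run_experiment_replication(cfg, n_participants = 12,
                                      conditions = c("Position1", "Position2"),
                                      classifier = cls$model)
    list(cfg = cfg, classifier = cls$model, holdout = hold, rep = rep)
  })
}
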