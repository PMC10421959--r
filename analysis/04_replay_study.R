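#!/usr/bin/env Rscript

# Deterministic bookkeeping replay of the published tailoring run: the
# printed per-term scores and per-step removal lists drive the pipeline from
# the 80-term library down to the final 30-term survey.

suppressPackageStartupMessages(library(proctailor))

out_dir <- "results/replay"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

r <- replay_study_tailoring()
write_ledger_json(r$ledger, file.path(out_dir, "ledger.json"))
writeLines(r$survey$report, file.path(out_dir, "report.md"))
utils::write.csv(data.frame(step = names(r$survivors), surviving = as.integer(r$survivors)),
                 file.path(out_dir, "survivors.csv"), row.names = FALSE, quote = FALSE)

print(r$ledger)
cat(sprintf("final survey: %d terms, %d domains, up to %d items\n",
            length(r$survey$term_ids), r$survey$n_domains, r$survey$item_count))
cat(sprintf("matches shipped tailored core library: %s\n",
            identical(sort(r$survey$term_ids), sort(tailored_core_library()$term_id))))
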