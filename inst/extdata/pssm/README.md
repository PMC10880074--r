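# PSSM matrix fixtures

`synthetic_ecf_minus35.tsv` / `synthetic_ecf_minus10.tsv` are *synthetic*
low-entropy toy matrices (the output of `toy_pssm_pair()`), bundled so the
file-based loaders and the command-line interface can be exercised without
any external data. They are not the promoter preferences of any real ECF
group.

File dialect: an optional header (`#type=counts|freqs|logprobs`,
`#motif_id=...`) followed by 4 tab-separated rows in A, C, G, T order, one
column per motif position. MEME minimal motif files are also accepted via
`read_meme_pssms()`.

To scan with real ECF promoter preferences (e.g. the published ECF02/ECF11
matrices), place each group's -35 and -10 matrix here in the same dialect
and load them with

```r
pair <- load_pssm_pair("ECF02_minus35.tsv", "ECF02_minus10.tsv",
                       ecf_group = "ECF02")
```
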