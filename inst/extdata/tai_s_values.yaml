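# Wobble-interaction penalties (s-values) for the expression-based tRNA
# adaptation index. These are the "initial", non-optimised selective
# constraints of dos Reis, Savva & Wernisch (2004) NAR 32:5036-5044;
# optimised s-values assume that highly expressed genes have optimal codon
# usage, which is exactly the hypothesis under test, so the initial vector
# is the default. Keys are the codon's third base; `watson_crick` penalises
# the cognate anticodon, `wobble` the single non-canonical decoder
# (G:T / I:C / I:A / T:G; inosine is written as its genomic A).
watson_crick:
  T: 0.0
  C: 0.0
  A: 0.0
  G: 0.0
wobble:
  T: 0.41
  C: 0.28
  A: 0.9999
  G: 0.68
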