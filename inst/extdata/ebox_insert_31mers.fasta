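>A_alcalica published 31-nt upstream fragment carrying the paired MyoD E-box
CAGGTGACTGTGATTATATAGTTCACAGGTG
>O_niloticus published 31-nt upstream fragment: one MyoD E-box plus presumptive CAGGTT site
CAGGTGACTGTGATTATATAGTTCACAGGTT
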