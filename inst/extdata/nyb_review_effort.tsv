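song_year	days_reviewed	hours_reviewed
1	90	270
2	145	435
3	157	471
4	169	507
5	92	276
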