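level,label,frequency
1,very_low,219
2,low,221
3,medium,217
4,high,221
5,very_high,219
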