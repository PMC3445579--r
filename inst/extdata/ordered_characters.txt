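1
7
8
10
13
25
38
39
42
43
47
50
56
58
69
86
87
96
126
132
133
151
152
154
156
166
179
181
182
183
184
198
202
214
218
225
228
230
231
237
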