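naics,potential
236220,medium
236115,medium
236118,medium
236116,medium
236117,medium
236210,medium
237310,high
237110,high
237130,high
237120,high
237210,high
237990,high
238212,medium
238222,medium
238221,medium
238211,mixed
238311,mixed
238321,mixed
238911,mixed
238912,mixed
238161,mixed
238312,mixed
238111,mixed
238351,mixed
238131,mixed
238992,mixed
238292,mixed
238991,mixed
238322,mixed
238162,mixed
238112,mixed
238171,mixed
238122,mixed
238331,mixed
238152,mixed
238341,mixed
238142,mixed
238392,mixed
238352,mixed
238141,mixed
238151,mixed
238192,mixed
238391,mixed
238132,mixed
238332,mixed
238121,mixed
238291,mixed
238191,mixed
238172,mixed
238342,mixed
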