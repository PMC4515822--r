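{"type":"Polygon","coordinates":[[[104,22],[122,22],[122,32],[104,32],[104,22]]]}
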