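# Healthy-baseline marmoset rest-activity preset (version 1)
name: baseline-marmoset
activity: {}
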