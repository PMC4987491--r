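"site_id","url","sponsor_type","health_item_count","exclusion_flags"
"site0001","https://example.org/site0001","government",7,""
"site0002","https://example.org/site0002","government",8,""
"site0003","https://example.org/site0003","for-profit",10,""
"site0004","https://example.org/site0004","nonprofit",6,""
"site0005","https://example.org/site0005","nonprofit",7,""
"site0006","https://example.org/site0006","nonprofit",10,""
"site0007","https://example.org/site0007","nonprofit",11,""
"site0008","https://example.org/site0008","for-profit",5,""
"site0009","https://example.org/site0009","nonprofit",7,""
"site0010","https://example.org/site0010","nonprofit",7,""
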