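"name","latitude","longitude","nonag_population"
"City01","30.640082822190799","119.46156813390552","6337637"
"City02","23.980579935028537","119.07212817808612","6582381"
"City03","23.095193218954499","116.85124599607663","781194"
"City04","31.093439767317797","116.30309634236619","2619029"
"City05","26.770481922812259","119.81425403524189","1685082"
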