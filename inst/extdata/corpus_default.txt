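The quick brown fox jumps over the lazy dog while the small grey cat
sleeps in the warm sun by the old stone wall. Every morning the people of
the town walk along the river to the market where they buy bread and milk
and fresh fruit from the farmers. The children play games in the park and
the teachers read stories about ships and stars and far away lands. When
the rain falls the streets are quiet and the lamps glow in the windows of
the houses. A good friend will always help you when you need a hand and a
kind word can make a hard day feel light. We learn to write and to speak
so that we can share our thoughts with the world. The doctor asked the
patient to describe how the pain began and the patient said that it
started after a long walk in the cold wind. Please bring me a glass of
water and a warm blanket. I would like to thank you for your help and for
your time. The family sat together at the table and talked about the
plans for the summer. Music filled the room as the band played and the
guests danced late into the night. The teacher wrote the answer on the
board and the students copied it into their books. A short message can
carry great meaning when it is chosen with care. The hello world of every
new writer begins with a single word typed one letter at a time. The cat
and the dog ran through the garden and the birds flew over the trees. My
name is on the list and I want to go home soon. Can you hear me now. Yes
I can hear you well. Thank you very much for this fine day. The water in
the lake was clear and cold and the boats moved slowly in the light wind.
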